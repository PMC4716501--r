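#' Configure the threshold-comparison experiment
#'
#' Assembles everything [run_experiment()] needs: landscape dimensions,
#' species panel, realization count, per-model training designs, the
#' threshold-selection datasets and the candidate-threshold rule. Two
#' presets are provided:
#' \describe{
#'   \item{`desk` (default)}{100 x 100 grid, 10 realizations per species,
#'     all sample sizes scaled by `n_cells / 62500` (with a floor of 25
#'     presences) while preserving every KP-RP ratio. Runs in minutes.}
#'   \item{`full`}{the full protocol: 250 x 250 grid (62,500 cells), 100
#'     realizations per species, 50 presences + 5000 random training
#'     points, test 3000, po1-po4 = (50,5000), (50,50), (5000,5000),
#'     (5000,50), pa1 5000. Several hours of compute.}
#' }
#'
#' Thresholds in the experiment are selected by exact argmax over each
#' scan's unique observed scores (the [threshold_scan()] default): model
#' families differ enormously in how their scores occupy \[0,1\] —
#' presence-background logistic fits concentrate fitted probabilities near
#' the presence fraction of the training table — so no fixed grid serves
#' all of them. `grid_step` (default 0.05) is instead the \emph{comparison}
#' resolution: the score-scale granularity at which selected thresholds
#' are considered equivalent when compared across selection datasets.
#'
#' @param preset `"desk"` or `"full"`.
#' @param rows,cols Grid dimensions; default from preset.
#' @param correlation 3 x 3 covariate correlation matrix.
#' @param smoothing_radius Spatial smoothing radius in cells (0 = none).
#' @param n_realizations Realizations per species; default from preset.
#' @param species_targets,species_slopes Species panel specification (see
#'   [default_species_panel()]).
#' @param models Model families to fit.
#' @param candidate_rule,grid_step Candidate-threshold rule for selection
#'   scans (see [threshold_scan()]).
#' @param base_seed Integer master seed; every random draw in the
#'   experiment derives deterministically from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "full"),
                              rows = NULL, cols = NULL,
                              correlation = diag(3),
                              smoothing_radius = 0,
                              n_realizations = NULL,
                              species_targets = c(0.10, 0.15, 0.25, 0.40, 0.55, 0.70),
                              species_slopes = default_species_slopes(length(species_targets)),
                              models = c("DOMAIN", "GLM", "MAXENT_LIKE", "RANDOM_FOREST"),
                              candidate_rule = "unique_scores",
                              grid_step = 0.05,
                              base_seed = 1L) {
  preset <- match.arg(preset)
  rows <- rows %||% if (preset == "desk") 100L else 250L
  cols <- cols %||% rows
  n_realizations <- n_realizations %||% if (preset == "desk") 10L else 100L
  models <- match.arg(models, c("DOMAIN", "GLM", "MAXENT_LIKE", "RANDOM_FOREST"),
                      several.ok = TRUE)
  if (preset == "full") {
    warning("full preset: 62,500 cells x 100 realizations; expect hours of compute")
  }
  structure(
    list(preset = preset, rows = as.integer(rows), cols = as.integer(cols),
         correlation = correlation, smoothing_radius = smoothing_radius,
         n_realizations = as.integer(n_realizations),
         species_targets = species_targets,
         species_slopes = as.matrix(species_slopes),
         models = models,
         candidate_rule = candidate_rule, grid_step = grid_step,
         base_seed = as.integer(base_seed),
         designs = scaled_designs(as.integer(rows) * as.integer(cols))),
    class = "experiment_config"
  )
}

#' Sample sizes scaled to a grid
#'
#' Scales the full-protocol sample sizes by `n_cells / 62500`, flooring
#' presence counts at 25 so that every design stays feasible on small
#' grids, and preserving each threshold-selection dataset's KP-RP ratio
#' exactly (background counts are derived from the scaled presence counts
#' and the target ratio). At `n_cells = 62500` this reproduces the full
#' protocol's counts exactly.
#'
#' @param n_cells Number of grid cells.
#' @return A list of per-design counts.
#' @export
scaled_designs <- function(n_cells) {
  scale <- n_cells / 62500
  n_small <- max(25L, as.integer(round(50 * scale)))   # train & po1/po2 presences
  n_big <- max(25L, as.integer(round(5000 * scale)))   # po3/po4 presences
  list(
    train = list(n_presence = n_small, n_background = 100L * n_small),
    train_rf = list(n_presence = n_small, n_background = 2L * n_small),
    test_total = max(100L, as.integer(round(3000 * scale))),
    po = list(
      po1 = c(n1val = n_small, nrpval = 100L * n_small),  # KP-RP = 0.01
      po2 = c(n1val = n_small, nrpval = n_small),         # KP-RP = 1
      po3 = c(n1val = n_big, nrpval = n_big),             # KP-RP = 1
      po4 = c(n1val = n_big, nrpval = max(1L, as.integer(round(n_big / 100))))  # KP-RP = 100
    ),
    pa_total = max(100L, as.integer(round(5000 * scale)))
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  d <- x$designs
  cat(sprintf("Experiment config (%s preset)\n", x$preset))
  cat(sprintf("  grid %d x %d (%d cells), %d species, %d realizations, models: %s\n",
              x$rows, x$cols, x$rows * x$cols, length(x$species_targets),
              x$n_realizations, paste(x$models, collapse = ", ")))
  cat(sprintf("  train %d+%d (RF %d+%d), test %d, pa1 %d\n",
              d$train$n_presence, d$train$n_background,
              d$train_rf$n_presence, d$train_rf$n_background,
              d$test_total, d$pa_total))
  for (nm in names(d$po)) {
    cat(sprintf("  %s: %d presences, %d random points (KP-RP %g)\n", nm,
                d$po[[nm]]["n1val"], d$po[[nm]]["nrpval"],
                d$po[[nm]]["n1val"] / d$po[[nm]]["nrpval"]))
  }
  cat(sprintf("  threshold candidates: %s (step %g), base seed %d\n",
              x$candidate_rule, x$grid_step, x$base_seed))
  invisible(x)
}

#' Serialize an experiment configuration
#'
#' Round-trips an `experiment_config` through JSON so that a run is fully
#' described by a plain-text manifest.
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `read_experiment_config` returns an `experiment_config`;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  keep <- c("preset", "rows", "cols", "correlation", "smoothing_radius",
            "n_realizations", "species_targets", "species_slopes", "models",
            "candidate_rule", "grid_step", "base_seed")
  jsonlite::write_json(config[keep], path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(preset = x$preset, rows = x$rows, cols = x$cols,
                    correlation = as.matrix(x$correlation),
                    smoothing_radius = x$smoothing_radius,
                    n_realizations = x$n_realizations,
                    species_targets = x$species_targets,
                    species_slopes = as.matrix(x$species_slopes),
                    models = x$models,
                    candidate_rule = x$candidate_rule,
                    grid_step = x$grid_step,
                    base_seed = x$base_seed)
}

#' Run the full threshold-comparison experiment
#'
#' For every species and realization: draws the training sets (standard and
#' the 2:1 Random Forest variant), the test set, the four presence-only
#' selection sets po1-po4 and the presence/absence selection set pa1; fits
#' every configured model family; selects thresholds with maxSSS on all
#' five selection datasets, maxF on pa1 and maxFpb on po1-po4; evaluates
#' each selected threshold on the independent test set (sensitivity,
#' specificity, TSS, F); records the model's test AUC and the
#' threshold-based prevalence estimate with its signed and absolute bias
#' against realized prevalence.
#'
#' Realizations and sample draws are shared across model families within a
#' (species, realization) cell, so model comparisons are paired. Every cell
#' uses its own seed stream derived from `base_seed`, making any cell
#' independently reproducible and the full record table byte-identical
#' across reruns. A cell whose sampling or fitting fails (e.g. a
#' realization with too few presences) is skipped with a warning carrying
#' full provenance; the run continues.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-species progress.
#' @return A data frame of class `experiment_records`, one row per species
#'   x realization x model x (selection dataset, criterion): columns
#'   `species, target_prevalence, realization, true_prevalence, model,
#'   dataset, criterion, threshold, criterion_value, auc, sensitivity,
#'   specificity, tss, f_measure, estimated_prevalence, signed_bias,
#'   absolute_bias`. The config is attached as attribute `"config"`.
#' @seealso [summarize_experiment()]
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  d <- config$designs
  env <- generate_environment(config$rows, config$cols, config$correlation,
                              config$smoothing_radius,
                              seed = mix_seed(config$base_seed, 1L))
  panel <- default_species_panel(env, config$species_targets, config$species_slopes)
  crossing <- selection_crossing()

  out <- vector("list", length(panel) * config$n_realizations)
  k <- 0L
  for (si in seq_along(panel)) {
    sp <- panel[[si]]
    surf <- suitability(env, sp)
    if (verbose) {
      message(sprintf("species %s (target prevalence %.2f)", sp$label,
                      sp$target_prevalence))
    }
    for (r in seq_len(config$n_realizations)) {
      k <- k + 1L
      cell_seed <- mix_seed(config$base_seed, si, r)
      out[[k]] <- tryCatch(
        run_cell(config, env, sp, surf, r, cell_seed, d, crossing),
        error = function(e) {
          warning(sprintf("skipping species %s realization %d: %s",
                          sp$label, r, conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_records()
  rownames(res) <- NULL
  attr(res, "config") <- config
  class(res) <- c("experiment_records", "data.frame")
  res
}

empty_records <- function() {
  data.frame(species = character(), target_prevalence = numeric(),
             realization = integer(), true_prevalence = numeric(),
             model = character(), dataset = character(), criterion = character(),
             threshold = numeric(), criterion_value = numeric(), auc = numeric(),
             sensitivity = numeric(), specificity = numeric(), tss = numeric(),
             f_measure = numeric(), estimated_prevalence = numeric(),
             signed_bias = numeric(), absolute_bias = numeric())
}

# The protocol's crossing of selection datasets and criteria.
selection_crossing <- function() {
  rbind(
    data.frame(dataset = c("pa1", "po1", "po2", "po3", "po4"), criterion = "maxSSS"),
    data.frame(dataset = "pa1", criterion = "maxF"),
    data.frame(dataset = c("po1", "po2", "po3", "po4"), criterion = "maxFpb")
  )
}

run_cell <- function(config, env, sp, surf, r, cell_seed, d, crossing) {
  real <- realize(surf, seed = mix_seed(cell_seed, 1L))
  train <- draw_training(real, env, d$train$n_presence, d$train$n_background,
                         seed = mix_seed(cell_seed, 2L))
  train_rf <- draw_training(real, env, d$train_rf$n_presence,
                            d$train_rf$n_background,
                            seed = mix_seed(cell_seed, 3L))
  # Exclusions operate on *labeled* cells: the training presences and the
  # fully labeled test set. Training background points are unlabeled random
  # locations and stay available to every later pool.
  train_pres <- rbind(train[train$label == "presence", ],
                      train_rf[train_rf$label == "presence", ])
  test <- draw_test(real, env, exclude = train_pres,
                    total = d$test_total, seed = mix_seed(cell_seed, 4L))
  sel_sets <- list(pa1 = draw_validation_pa(real, env, train_pres, test,
                                            total = d$pa_total,
                                            seed = mix_seed(cell_seed, 5L)))
  for (i in seq_along(d$po)) {
    nm <- names(d$po)[i]
    sel_sets[[nm]] <- draw_validation_po(real, env, train_pres, test,
                                         n1val = d$po[[i]]["n1val"],
                                         nrpval = d$po[[i]]["nrpval"],
                                         seed = mix_seed(cell_seed, 5L + i),
                                         role = nm)
  }

  rows <- vector("list", length(config$models))
  for (mi in seq_along(config$models)) {
    fam <- config$models[mi]
    tr <- if (fam == "RANDOM_FOREST") train_rf else train
    fit <- fit_sdm(tr, fam, seed = mix_seed(cell_seed, 20L + mi))
    scored_test <- score_set(fit, test)
    auc_val <- auc(scored_test)
    scans <- lapply(sel_sets, function(s) {
      threshold_scan(score_set(fit, s),
                     candidate_rule = config$candidate_rule,
                     step = config$grid_step)
    })
    recs <- lapply(seq_len(nrow(crossing)), function(i) {
      ch <- select_threshold(scans[[crossing$dataset[i]]], crossing$criterion[i])
      ev <- evaluate_threshold(scored_test, ch$threshold)
      est <- estimate_prevalence(scored_test, ch$threshold)
      data.frame(
        species = sp$label, target_prevalence = sp$target_prevalence,
        realization = r, true_prevalence = real$realized_prevalence,
        model = fam, dataset = crossing$dataset[i],
        criterion = crossing$criterion[i],
        threshold = ch$threshold, criterion_value = ch$value,
        auc = auc_val,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        tss = ev$tss, f_measure = ev$f_measure,
        estimated_prevalence = est,
        signed_bias = est - real$realized_prevalence,
        absolute_bias = abs(est - real$realized_prevalence)
      )
    })
    rows[[mi]] <- do.call(rbind, recs)
  }
  do.call(rbind, rows)
}

#' Summarize experiment records
#'
#' Per-cell medians and interquartile ranges of the selected threshold and
#' the test-set metrics, grouped by species, model, selection dataset and
#' criterion — the grouping of the protocol's comparison figures.
#'
#' @param records An `experiment_records` data frame.
#' @return A data frame with one row per (species, model, dataset,
#'   criterion) and `*_median` / `*_iqr` columns for threshold,
#'   sensitivity, specificity, tss, f_measure, estimated_prevalence and
#'   signed_bias, plus `auc_median` and the record count `n`.
#' @export
summarize_experiment <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  vars <- c("threshold", "sensitivity", "specificity", "tss", "f_measure",
            "estimated_prevalence", "signed_bias")
  key <- interaction(records$species, records$model, records$dataset,
                     records$criterion, drop = TRUE)
  groups <- split(records, key)
  out <- lapply(groups, function(g) {
    row <- data.frame(species = g$species[1L],
                      target_prevalence = g$target_prevalence[1L],
                      model = g$model[1L], dataset = g$dataset[1L],
                      criterion = g$criterion[1L], n = nrow(g))
    for (v in vars) {
      row[[paste0(v, "_median")]] <- stats::median(g[[v]], na.rm = TRUE)
      row[[paste0(v, "_iqr")]] <- stats::IQR(g[[v]], na.rm = TRUE)
    }
    row$auc_median <- stats::median(g$auc, na.rm = TRUE)
    row
  })
  res <- do.call(rbind, out)
  res <- res[order(res$target_prevalence, res$model, res$criterion, res$dataset), ]
  rownames(res) <- NULL
  res
}

#' @export
print.experiment_records <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Experiment records: %d rows\n", nrow(x)))
  if (!is.null(cfg)) {
    cat(sprintf("  %s preset, %d x %d grid, %d species x %d realizations x %d models\n",
                cfg$preset, cfg$rows, cfg$cols, length(cfg$species_targets),
                cfg$n_realizations, length(cfg$models)))
  }
  NextMethod()
}
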