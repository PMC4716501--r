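#' @title Sampling designs for training, testing and threshold selection
#'
#' @description
#' These functions build the datasets of the simulation protocol from a
#' realized species distribution:
#' \itemize{
#'   \item [draw_training()]: known presences plus random background points
#'     used to fit the distribution models;
#'   \item [draw_test()]: an independent presence/absence test set whose
#'     composition matches the realized prevalence;
#'   \item [draw_validation_po()]: presence-only threshold selection sets
#'     (presences + random points) with a controllable ratio of known
#'     presences to random points (the KP-RP ratio);
#'   \item [draw_validation_pa()]: a presence/absence threshold selection set.
#' }
#' All sets are plain data frames of class `sample_set` with columns
#' `cell_id, x1, x2, x3, label, role`; presence-only sets carry their KP-RP
#' ratio as attribute `kp_rp_ratio`. Presences are only ever drawn from
#' occupied cells, absences only from unoccupied cells, and background
#' ("random") points from all cells regardless of occupancy — a fraction of
#' them equal to the prevalence is therefore truly occupied, which is the
#' crux of presence-background evaluation. All draws are without
#' replacement within a set and fully determined by `seed`.
#'
#' @name sampling_designs
NULL

new_sample_set <- function(cell_id, env, label, role, kp_rp_ratio = NA_real_) {
  x <- env$covariates[cell_id, , drop = FALSE]
  out <- data.frame(cell_id = cell_id,
                    x1 = x[, 1L], x2 = x[, 2L], x3 = x[, 3L],
                    label = label, role = role,
                    row.names = NULL)
  attr(out, "kp_rp_ratio") <- kp_rp_ratio
  class(out) <- c("sample_set", "data.frame")
  out
}

#' @export
print.sample_set <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("Sample set '%s': %d points (%s)\n",
              x$role[1L] %||% "?", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  r <- attr(x, "kp_rp_ratio")
  if (!is.na(r)) cat(sprintf("  KP-RP ratio: %g\n", r))
  invisible(x)
}

collect_cell_ids <- function(exclude) {
  if (is.null(exclude)) return(integer())
  if (is.data.frame(exclude)) return(unique(exclude$cell_id))
  unique(unlist(lapply(exclude, function(e) e$cell_id)))
}

#' Draw a model-training sample (presences + random background)
#'
#' Selects `n_presence` occupied cells uniformly without replacement as
#' known presences and `n_background` cells uniformly from the whole grid
#' as random background points. The defaults follow the protocol of 50
#' presences and 5000 random points; Random Forest training uses a 2:1
#' background:presence ratio instead (pass `n_background = 2 * n_presence`),
#' since that model family loses accuracy when background dominates.
#'
#' @param realization A `realization`.
#' @param env The `env_grid` the realization lives on.
#' @param n_presence,n_background Sample sizes (positive integers).
#' @param seed Integer seed.
#' @return A `sample_set` with role `"train"`, labels
#'   `"presence"`/`"background"`.
#' @family sampling designs
#' @export
draw_training <- function(realization, env, n_presence = 50L,
                          n_background = 5000L, seed = 1L) {
  stopifnot(inherits(realization, "realization"), inherits(env, "env_grid"))
  if (n_presence < 1L) stop("`n_presence` must be at least 1", call. = FALSE)
  if (n_background < 1L) stop("`n_background` must be at least 1", call. = FALSE)
  occupied <- which(realization$occupancy == 1L)
  if (length(occupied) < n_presence) {
    stop(sprintf(
      "cannot draw %d presences: realization has only %d occupied cells (realized prevalence %.4f)",
      n_presence, length(occupied), realization$realized_prevalence), call. = FALSE)
  }
  ids <- with_seed(seed, {
    p <- sample(occupied, n_presence)
    b <- sample(env$n_cells, n_background)
    list(p = p, b = b)
  })
  new_sample_set(c(ids$p, ids$b), env,
                 label = rep(c("presence", "background"),
                             c(n_presence, n_background)),
                 role = "train",
                 kp_rp_ratio = n_presence / n_background)
}

# Shared machinery for prevalence-proportional presence/absence sets.
draw_pa_like <- function(realization, env, exclude, total, seed, role) {
  stopifnot(inherits(realization, "realization"), inherits(env, "env_grid"))
  if (total < 2L) stop("`total` must be at least 2", call. = FALSE)
  pi_hat <- realization$realized_prevalence
  n1 <- round(total * pi_hat)          # round half to even; remainder to absences
  n0 <- total - n1
  excl <- collect_cell_ids(exclude)
  occupied <- setdiff(which(realization$occupancy == 1L), excl)
  unoccupied <- setdiff(which(realization$occupancy == 0L), excl)
  if (length(occupied) < n1 || length(unoccupied) < n0) {
    stop(sprintf(
      "insufficient cells after exclusion for role '%s': need %d presences (have %d) and %d absences (have %d)",
      role, n1, length(occupied), n0, length(unoccupied)), call. = FALSE)
  }
  ids <- with_seed(seed, {
    p <- sample(occupied, n1)
    a <- sample(unoccupied, n0)
    list(p = p, a = a)
  })
  new_sample_set(c(ids$p, ids$a), env,
                 label = rep(c("presence", "absence"), c(n1, n0)),
                 role = role)
}

#' Draw the independent presence/absence test set
#'
#' Selects `round(total * pi)` presences and the remaining absences from
#' cells not contained in `exclude` (the training data), where `pi` is the
#' realized prevalence. With the default `total = 3000` this reproduces the
#' 3000 pi / 3000 (1 - pi) test design. Fractional counts round half to
#' even, with the remainder going to the absence class.
#'
#' @inheritParams draw_training
#' @param exclude A `sample_set` (or list of them) whose cells must not be
#'   sampled — normally the training set(s).
#' @param total Total test points.
#' @return A `sample_set` with role `"test"`, labels
#'   `"presence"`/`"absence"`.
#' @family sampling designs
#' @export
draw_test <- function(realization, env, exclude, total = 3000L, seed = 1L) {
  draw_pa_like(realization, env, exclude, total, seed, role = "test")
}

#' Draw a presence-only threshold selection set (po1-po4)
#'
#' Selects `n1val` presences from the occupied cells excluding the training
#' and test data, and `nrpval` random points from the full grid with no
#' exclusion (a random point may fall on an occupied cell, or even on a
#' cell used elsewhere — that is inherent to background sampling). The
#' protocol's four datasets are `(n1val, nrpval)` = (50, 5000), (50, 50),
#' (5000, 5000) and (5000, 50), termed po1-po4, with KP-RP ratios 0.01, 1,
#' 1 and 100.
#'
#' @inheritParams draw_training
#' @param exclude_train,exclude_test Sample sets whose cells are excluded
#'   from the presence draw.
#' @param n1val Number of known presences.
#' @param nrpval Number of random points; must be positive (the KP-RP
#'   ratio is undefined otherwise).
#' @param role Role tag for the returned set (e.g. `"po1"`).
#' @return A `sample_set` with labels `"presence"`/`"background"` and
#'   attribute `kp_rp_ratio = n1val / nrpval`.
#' @family sampling designs
#' @export
draw_validation_po <- function(realization, env, exclude_train, exclude_test,
                               n1val, nrpval, seed = 1L, role = "po") {
  stopifnot(inherits(realization, "realization"), inherits(env, "env_grid"))
  n1val <- as.integer(unname(n1val))
  nrpval <- as.integer(unname(nrpval))
  if (n1val < 1L) stop("`n1val` must be at least 1", call. = FALSE)
  if (nrpval < 1L) stop("`nrpval` must be at least 1 (KP-RP ratio undefined otherwise)",
                        call. = FALSE)
  excl <- unique(c(collect_cell_ids(exclude_train), collect_cell_ids(exclude_test)))
  occupied <- setdiff(which(realization$occupancy == 1L), excl)
  if (length(occupied) < n1val) {
    stop(sprintf(
      "insufficient presences for role '%s': need %d, have %d after excluding train/test (realized prevalence %.4f)",
      role, n1val, length(occupied), realization$realized_prevalence), call. = FALSE)
  }
  ids <- with_seed(seed, {
    p <- sample(occupied, n1val)
    b <- sample(env$n_cells, nrpval)
    list(p = p, b = b)
  })
  new_sample_set(c(ids$p, ids$b), env,
                 label = rep(c("presence", "background"), c(n1val, nrpval)),
                 role = role,
                 kp_rp_ratio = n1val / nrpval)
}

#' Draw the presence/absence threshold selection set (pa1)
#'
#' As [draw_test()] but excluding both the training and test data and with
#' a default total of 5000 points: `round(total * pi)` presences and the
#' remainder absences.
#'
#' @inheritParams draw_validation_po
#' @param total Total points.
#' @return A `sample_set` with role `"pa1"`.
#' @family sampling designs
#' @export
draw_validation_pa <- function(realization, env, exclude_train, exclude_test,
                               total = 5000L, seed = 1L) {
  draw_pa_like(realization, env, list(exclude_train, exclude_test),
               total, seed, role = "pa1")
}

#' Read and write sample sets as CSV
#'
#' Columns: `cell_id, x1, x2, x3, label, role`; the KP-RP ratio is restored
#' from the label counts on read.
#'
#' @param x A `sample_set`.
#' @param path File path.
#' @return `read_sample_set` returns a `sample_set`; `write_sample_set`
#'   returns `path` invisibly.
#' @export
write_sample_set <- function(x, path) {
  stopifnot(inherits(x, "sample_set"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "x1", "x2", "x3", "label", "role") %in% names(d)))
  n_bg <- sum(d$label == "background")
  ratio <- if (n_bg > 0) sum(d$label == "presence") / n_bg else NA_real_
  attr(d, "kp_rp_ratio") <- ratio
  class(d) <- c("sample_set", "data.frame")
  d
}
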