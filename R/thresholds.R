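#' Scan candidate thresholds over a scored sample set
#'
#' Computes confusion counts and all derived metrics at every candidate
#' threshold, using the fixed prediction convention
#' \strong{score >= threshold => predicted presence}. By default the
#' candidates are the unique observed scores plus a below-minimum and an
#' above-maximum sentinel (so both the "everything present" and "nothing
#' present" rows are on the table); the argmax over unique scores is exact.
#' Alternatively a fixed grid on \[0,1\] can be used, which makes
#' thresholds selected from different datasets directly comparable and
#' suits score distributions with heavy ties.
#'
#' The scan's `data_kind` is `"pa"` when the non-presence points are true
#' absences and `"po"` when they are random background points; in the
#' latter case `fp`/`tn` (and everything built from them) are pseudo-counts
#' over the background.
#'
#' @param scored A `scored_set` (see [score_set()]) with at least one
#'   presence and one absence/background point.
#' @param candidate_rule `"unique_scores"` (default) or `"grid"`.
#' @param step Grid step in score units when `candidate_rule = "grid"`.
#' @return An object of class `threshold_scan`: list with `table` (one row
#'   per candidate: `threshold, tp, fn, fp, tn, Se, Sp, SSS, TSS,
#'   precision, F, p_pp, r_prime, Fpb`), `data_kind`, `candidate_rule`,
#'   `n_presence`, `n_background`.
#' @seealso [select_threshold()]
#' @export
threshold_scan <- function(scored, candidate_rule = c("unique_scores", "grid"),
                           step = 0.001) {
  candidate_rule <- match.arg(candidate_rule)
  stopifnot(is.data.frame(scored), "score" %in% names(scored))
  is_pres <- scored$label == "presence"
  n1 <- sum(is_pres)
  n0 <- sum(!is_pres)
  if (n1 == 0L || n0 == 0L) {
    stop("scan needs at least one presence and one absence/background point",
         call. = FALSE)
  }
  data_kind <- if (any(scored$label == "background")) "po" else "pa"

  sp <- sort(scored$score[is_pres])
  sb <- sort(scored$score[!is_pres])
  cand <- if (candidate_rule == "unique_scores") {
    u <- sort(unique(scored$score))
    c(u[1L] - 1e-6, u, u[length(u)] + 1e-6)
  } else {
    if (step <= 0 || step > 1) stop("`step` must be in (0, 1]", call. = FALSE)
    g <- seq(0, 1, by = step)
    c(g, 1 + step)
  }

  # scores >= t are predicted present; findInterval(..., left.open) counts < t
  tp <- n1 - findInterval(cand, sp, left.open = TRUE)
  fp <- n0 - findInterval(cand, sb, left.open = TRUE)
  fn <- n1 - tp
  tn <- n0 - fp

  se <- tp / n1
  spv <- tn / n0
  tab <- data.frame(
    threshold = cand, tp = tp, fn = fn, fp = fp, tn = tn,
    Se = se, Sp = spv, SSS = se + spv, TSS = se + spv - 1,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    F = f_measure_vec(tp, fn, fp),
    p_pp = ifelse(fp > 0, tp / fp, ifelse(tp > 0, Inf, NA_real_)),
    r_prime = se,
    Fpb = f_pb_vec(tp, fn, fp)
  )
  structure(
    list(table = tab, data_kind = data_kind, candidate_rule = candidate_rule,
         step = if (candidate_rule == "grid") step else NA_real_,
         n_presence = n1, n_background = n0),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan (%s data): %d candidates over %d presences and %d %s\n",
              x$data_kind, nrow(x$table), x$n_presence, x$n_background,
              if (x$data_kind == "po") "background points" else "absences"))
  cat(sprintf("  candidate rule: %s\n", x$candidate_rule))
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, metrics = c("Se", "Sp", "TSS"), ...) {
  tab <- x$table
  graphics::matplot(tab$threshold, tab[, metrics, drop = FALSE], type = "l",
                    lty = 1, xlab = "threshold", ylab = "metric", ...)
  graphics::legend("right", legend = metrics, col = seq_along(metrics), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Select a threshold by maximizing a criterion
#'
#' Picks the candidate threshold maximizing the chosen criterion over a
#' [threshold_scan()]:
#' \describe{
#'   \item{`maxSSS`}{maximum of Se + Sp. Valid on both presence/absence and
#'     presence-only scans — the presence-only SSS is an increasing linear
#'     transform of the presence/absence SSS (see [sss_identity()]), so the
#'     argmax is the same and the formula needs no adjustment.}
#'   \item{`maxF`}{maximum of the F measure; presence/absence scans only.}
#'   \item{`maxFpb`}{maximum of the presence-background surrogate F_pb;
#'     presence-only scans only.}
#' }
#' Candidates at which the criterion is undefined (`NA`) are excluded from
#' the argmax. Exact ties are broken toward the \emph{smallest} threshold,
#' which favours sensitivity — the conservative choice for rare species,
#' where omission errors cost more than commission errors.
#'
#' @param scan A `threshold_scan`.
#' @param criterion One of `"maxSSS"`, `"maxF"`, `"maxFpb"`.
#' @return An object of class `threshold_choice`: list with `threshold`,
#'   `value` (the achieved criterion value), `criterion` and `data_kind`.
#' @export
select_threshold <- function(scan, criterion = c("maxSSS", "maxF", "maxFpb")) {
  stopifnot(inherits(scan, "threshold_scan"))
  criterion <- match.arg(criterion)
  if (criterion == "maxF" && scan$data_kind != "pa") {
    stop("maxF applies to presence/absence scans only; use maxFpb for presence-only data",
         call. = FALSE)
  }
  if (criterion == "maxFpb" && scan$data_kind != "po") {
    stop("maxFpb applies to presence-only scans only; use maxF for presence/absence data",
         call. = FALSE)
  }
  vals <- switch(criterion,
                 maxSSS = scan$table$SSS,
                 maxF = scan$table$F,
                 maxFpb = scan$table$Fpb)
  ok <- !is.na(vals)
  if (!any(ok)) stop("criterion is undefined at every candidate threshold", call. = FALSE)
  # candidates are sorted ascending, so which.max lands on the smallest
  # threshold among exact ties
  idx <- which(ok)[which.max(vals[ok])]
  structure(
    list(threshold = scan$table$threshold[idx], value = vals[idx],
         criterion = criterion, data_kind = scan$data_kind),
    class = "threshold_choice"
  )
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat(sprintf("%s threshold = %.6g (achieved %s = %.6g, %s data)\n",
              x$criterion, x$threshold,
              sub("max", "", x$criterion), x$value, x$data_kind))
  invisible(x)
}

#' Export a threshold scan table to CSV
#'
#' @param scan A `threshold_scan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_threshold_scan <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  utils::write.csv(scan$table, path, row.names = FALSE)
  invisible(path)
}
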