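#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of continuous scores against binary
#' labels, with ties counted 1/2. Invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Either a `scored_set` or a numeric score vector.
#' @param labels Ignored for a `scored_set`; otherwise a logical/0-1 vector
#'   marking the positive (presence) class.
#' @return AUC in \[0,1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, labels = NULL) {
  if (inherits(scores, "scored_set")) {
    labels <- scores$label == "presence"
    scores <- scores$score
  }
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # average ranks give the 1/2 tie convention
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based prevalence estimate
#'
#' The fraction of evaluation points predicted present, i.e. with score at
#' or above the threshold. Applied to a scored full-grid set this is the
#' predicted area of presence relative to the total study area.
#'
#' @param scored A `scored_set` or numeric score vector.
#' @param threshold Score cutoff; `score >= threshold` counts as predicted
#'   presence.
#' @return Estimated prevalence in \[0,1\].
#' @export
estimate_prevalence <- function(scored, threshold) {
  s <- if (is.data.frame(scored)) scored$score else as.numeric(scored)
  if (length(s) == 0L) stop("cannot estimate prevalence from an empty set", call. = FALSE)
  mean(s >= threshold)
}

#' Evaluate a thresholded prediction on labelled data
#'
#' Builds the confusion matrix of `score >= threshold` against the true
#' labels and returns the headline metrics.
#'
#' @param scored A `scored_set` with presence and absence (or background)
#'   labels.
#' @param threshold Score cutoff.
#' @return A list with `counts` (a [confusion_counts()]), `sensitivity`,
#'   `specificity`, `tss` and `f_measure`.
#' @export
evaluate_threshold <- function(scored, threshold) {
  stopifnot(is.data.frame(scored), "score" %in% names(scored))
  pred <- scored$score >= threshold
  pres <- scored$label == "presence"
  cc <- confusion_counts(tp = sum(pred & pres), fn = sum(!pred & pres),
                         fp = sum(pred & !pres), tn = sum(!pred & !pres))
  list(counts = cc,
       sensitivity = sensitivity(cc),
       specificity = specificity(cc),
       tss = tss(cc),
       f_measure = f_measure(cc))
}

#' Correlation between model accuracy and prevalence-estimation bias
#'
#' Spearman rank correlation between AUC and the absolute bias of the
#' threshold-based prevalence estimate across experiment records
#' (by default the maxF / pa1 records, where the effect is diagnosed). A
#' strongly negative correlation means only highly accurate models yield
#' usable prevalence estimates. The p-value uses the large-sample t
#' approximation above n = 30 and the exact distribution below.
#'
#' @param records An experiment record data frame (see [run_experiment()]).
#' @param criterion,dataset Record subset to correlate.
#' @return A list with `rho`, `p_value` and `n`.
#' @export
bias_vs_auc <- function(records, criterion = "maxF", dataset = "pa1") {
  d <- records[records$criterion == criterion & records$dataset == dataset, ]
  d <- d[is.finite(d$auc) & is.finite(d$absolute_bias), ]
  if (nrow(d) < 10L) stop("need at least 10 records", call. = FALSE)
  if (stats::sd(d$auc) == 0 || stats::sd(d$absolute_bias) == 0) {
    warning("constant AUC or bias column: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  ct <- suppressWarnings(
    stats::cor.test(d$auc, d$absolute_bias, method = "spearman",
                    exact = nrow(d) <= 30L)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}
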