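#' Confusion counts
#'
#' Bundle of the four confusion-matrix cells at a threshold. For
#' presence/absence data all four cells are true counts; for
#' presence-background data `fp` and `tn` are pseudo-counts computed over
#' the random background points (predicted presences, respectively
#' predicted absences, among all background points).
#'
#' @param tp,fn,fp,tn Nonnegative integer counts: true presences, false
#'   absences, (pseudo-)false presences, (pseudo-)true absences.
#' @return An object of class `confusion_counts`.
#' @seealso [sensitivity()], [specificity()], [tss()], [f_measure()],
#'   [f_pb()]
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: tp = %d, fn = %d, fp = %d, tn = %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Accuracy metrics from confusion counts
#'
#' Standard threshold-dependent metrics:
#' \describe{
#'   \item{sensitivity (Se, recall r)}{`tp / (tp + fn)` — proportion of true
#'     presences predicted present.}
#'   \item{specificity (Sp)}{`tn / (fp + tn)` — proportion of (pseudo-)
#'     absences predicted absent.}
#'   \item{TSS}{true skill statistic, `Se + Sp - 1`, in \[-1, 1\].}
#'   \item{F}{harmonic mean of precision `p = tp / (tp + fp)` and recall,
#'     `2 p r / (p + r)`. Undefined (`NA`) when nothing is predicted
#'     present (`tp + fp = 0`); 0 when `tp = 0` but `fp > 0`.}
#' }
#' A metric whose denominator is zero returns `NA`.
#'
#' @param cc A [confusion_counts()] object.
#' @return A numeric scalar (possibly `NA` when undefined).
#' @export
sensitivity <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_ratio(cc$tp, cc$tp + cc$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_ratio(cc$tn, cc$fp + cc$tn)
}

#' @rdname sensitivity
#' @export
tss <- function(cc) {
  sensitivity(cc) + specificity(cc) - 1
}

#' @rdname sensitivity
#' @export
f_measure <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  f_measure_vec(cc$tp, cc$fn, cc$fp)
}

#' Presence-background F surrogate
#'
#' The presence-background counterpart of the F measure:
#' \deqn{F_{pb} = 2 p'' r' / (p'' + r')}
#' the harmonic mean of the presence-only recall `r' = tp / (tp + fn)` and
#' `p'' = tp / fp`, the ratio of correctly predicted presences to the
#' predicted presences among the random points. `p''` is a ratio, not a
#' proportion, and can exceed 1 — hence so can `F_pb`. Limits: `tp = 0`
#' gives 0; `fp = 0` with `tp > 0` gives the limit `2 r'` (as `p''` grows
#' without bound).
#'
#' @param cc A [confusion_counts()] object with `fp`/`tn` computed over
#'   background points.
#' @return A nonnegative numeric scalar (may exceed 1).
#' @seealso [fpb_from_precision_recall()] for the form parameterized by the
#'   presence/background calibration constant c.
#' @export
f_pb <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  f_pb_vec(cc$tp, cc$fn, cc$fp)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

# Vectorized versions used by the threshold scan.
f_measure_vec <- function(tp, fn, fp) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  r <- tp / (tp + fn)
  ifelse(is.na(p), NA_real_,
         ifelse(tp == 0, 0, 2 * p * r / (p + r)))
}

f_pb_vec <- function(tp, fn, fp) {
  r1 <- tp / (tp + fn)
  ifelse(tp == 0, 0,
         ifelse(fp == 0, 2 * r1,
                2 * (tp / fp) * r1 / (tp / fp + r1)))
}

#' Presence-only identities for SSS and TSS
#'
#' When random background points replace true absences, a fraction `s` of
#' the pseudo-absences (equal to the species prevalence under uniform
#' random sampling) is truly occupied. The presence-only sum of sensitivity
#' and specificity and true skill statistic then relate exactly to their
#' presence/absence counterparts:
#' \deqn{SSS' = s + (1 - s)\,SSS, \qquad TSS' = (1 - s)\,TSS.}
#' Both are strictly increasing in the presence/absence value for any fixed
#' `s < 1`, which is why maximizing SSS on presence-only data selects the
#' same threshold as on presence/absence data.
#'
#' @param s Contamination proportion in \[0,1\]: the fraction of truly
#'   occupied cells among the pseudo-absences.
#' @param sss_pa,tss_pa Presence/absence SSS (= Se + Sp) or TSS value.
#' @return The presence-only counterpart.
#' @export
sss_identity <- function(s, sss_pa) {
  check_s(s)
  s + (1 - s) * sss_pa
}

#' @rdname sss_identity
#' @export
tss_identity <- function(s, tss_pa) {
  check_s(s)
  (1 - s) * tss_pa
}

check_s <- function(s) {
  if (any(s < 0 | s > 1)) stop("`s` must lie in [0, 1]", call. = FALSE)
  invisible(s)
}

#' Presence/background calibration constant c
#'
#' The constant linking the background-based ratio `p''` to true precision
#' `p` via `p = p'' / c`, where
#' \deqn{c = n_1 / (\pi n_0)}
#' with `n1` known presences, `n0` random points and prevalence `pi`. `c`
#' equals 1 exactly when the number of known presences matches the expected
#' number of true presences among the random points — and it changes every
#' time the KP-RP ratio of the dataset changes, which is what makes the
#' F_pb criterion dataset-dependent.
#'
#' @param n1 Number of known presences.
#' @param n0 Number of random (background) points.
#' @param prevalence Species prevalence, strictly in (0,1).
#' @return An object of class `c_ratio` with fields `n1`, `n0`,
#'   `prevalence` and `c`.
#' @export
c_ratio <- function(n1, n0, prevalence) {
  stopifnot(n1 > 0, n0 > 0, prevalence > 0, prevalence < 1)
  structure(list(n1 = n1, n0 = n0, prevalence = prevalence,
                 c = n1 / (prevalence * n0)),
            class = "c_ratio")
}

#' @export
print.c_ratio <- function(x, ...) {
  cat(sprintf("c = n1 / (pi * n0) = %d / (%.4f * %d) = %.4f\n",
              x$n1, x$prevalence, x$n0, x$c))
  invisible(x)
}

#' F_pb as a function of precision, recall and c
#'
#' For large samples the presence-only recall equals the true recall, and
#' substituting `p'' = c p` into the harmonic mean gives
#' \deqn{F_{pb} = 2 p r / (p + r / c).}
#' Limits: `c = 1` recovers the F measure `2 p r / (p + r)` exactly, and
#' `c` growing without bound gives `2 r`. Between those extremes the same
#' model evaluated with different KP-RP ratios is judged by genuinely
#' different criteria that merely share the name.
#'
#' @param p Precision in (0,1\].
#' @param r Recall in (0,1\].
#' @param c A [c_ratio()] object or a positive number.
#' @return The value of F_pb.
#' @export
fpb_from_precision_recall <- function(p, r, c) {
  cval <- if (inherits(c, "c_ratio")) c$c else as.numeric(c)
  stopifnot(all(p > 0 & p <= 1), all(r > 0 & r <= 1), all(cval > 0))
  2 * p * r / (p + r / cval)
}
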