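# Shared fixtures and independent oracles for the test suite.

# Minimal sample-set-like data frame; fitting and scanning functions only
# require the covariate, label and role columns.
make_set <- function(x, label, role = "train") {
  x <- matrix(x, ncol = 3)
  d <- data.frame(cell_id = seq_len(nrow(x)),
                  x1 = x[, 1], x2 = x[, 2], x3 = x[, 3],
                  label = label, role = role)
  class(d) <- c("sample_set", "data.frame")
  d
}

# Scored set straight from scores + labels (bypasses any model).
make_scored <- function(scores, labels, role = "pa1") {
  d <- data.frame(cell_id = seq_along(scores),
                  x1 = 0, x2 = 0, x3 = 0,
                  label = labels, role = role, score = scores)
  class(d) <- c("scored_set", "sample_set", "data.frame")
  d
}

# Wrap a bare covariate matrix as an environment grid for direct control of
# cell values in closed-form tests.
fake_env <- function(x) {
  x <- matrix(x, ncol = 3)
  colnames(x) <- c("x1", "x2", "x3")
  structure(list(covariates = x, rows = nrow(x), cols = 1L,
                 n_cells = nrow(x), correlation = diag(3),
                 smoothing_radius = 0, seed = NA_integer_),
            class = "env_grid")
}

# --- independent oracles -----------------------------------------------------

# O(n) per cutoff confusion counts by direct comparison (no sorting tricks).
oracle_counts <- function(scores, labels, t) {
  pres <- labels == "presence"
  pred <- scores >= t
  c(tp = sum(pred & pres), fn = sum(!pred & pres),
    fp = sum(pred & !pres), tn = sum(!pred & !pres))
}

# Exhaustive argmax over all cutoffs (unique scores + sentinels), computing
# each criterion from scalar first-principles formulas; smallest threshold
# wins ties. Returns list(threshold, value).
oracle_select <- function(scores, labels, criterion) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1e-6, u, u[length(u)] + 1e-6)
  best_t <- NA_real_
  best_v <- -Inf
  for (t in cand) {
    cc <- oracle_counts(scores, labels, t)
    tp <- cc["tp"]; fn <- cc["fn"]; fp <- cc["fp"]; tn <- cc["tn"]
    v <- switch(criterion,
      maxSSS = tp / (tp + fn) + tn / (fp + tn),
      maxF = {
        if (tp + fp == 0) NA_real_
        else if (tp == 0) 0
        else {
          p <- tp / (tp + fp); r <- tp / (tp + fn)
          2 * p * r / (p + r)
        }
      },
      maxFpb = {
        r1 <- tp / (tp + fn)
        if (tp == 0) 0
        else if (fp == 0) 2 * r1
        else {
          ppp <- tp / fp
          2 * ppp * r1 / (ppp + r1)
        }
      })
    if (!is.na(v) && v > best_v) {
      best_v <- v
      best_t <- t
    }
  }
  list(threshold = unname(best_t), value = unname(best_v))
}

# AUC by exhaustive pair counting with the 1/2 tie convention.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}
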