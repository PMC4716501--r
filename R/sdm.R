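#' Fit a species distribution model on a training sample
#'
#' Dispatches to one of four model families, each returning an object of
#' class `sdm_model` whose [predict()] method maps covariate vectors to
#' suitability scores on a common \[0,1\] scale:
#'
#' \describe{
#'   \item{`DOMAIN`}{presence-only environmental envelope: a site's score is
#'     its maximum Gower similarity to any training presence
#'     (range-standardized mean absolute covariate difference), clipped to
#'     \[0,1\]. See [fit_domain()].}
#'   \item{`GLM`}{binomial logistic regression of presence (1) versus
#'     background (0) on the three covariates; score = fitted probability.
#'     See [fit_glm()].}
#'   \item{`MAXENT_LIKE`}{ridge-penalized logistic regression on linear plus
#'     quadratic features (squares and pairwise products), the penalized
#'     presence-background formulation that Maxent's machinery reduces to;
#'     score = fitted probability. See [fit_maxent_like()].}
#'   \item{`RANDOM_FOREST`}{classification forest of presence versus
#'     background; score = fraction of trees voting presence. See
#'     [fit_random_forest()].}
#' }
#'
#' @param train A `sample_set` with presence and (except DOMAIN) background
#'   points.
#' @param family One of `"DOMAIN"`, `"GLM"`, `"MAXENT_LIKE"`,
#'   `"RANDOM_FOREST"`.
#' @param ... Passed to the family-specific fitting function.
#' @param seed Integer seed for the stochastic families (Random Forest
#'   bootstrap, Maxent-like CV folds); ignored by DOMAIN and GLM.
#' @return An `sdm_model`.
#' @examples
#' env <- generate_environment(30, 30, seed = 1)
#' sp <- species_definition(c(-1, 1.5, -0.9, 0.5))
#' re <- realize(suitability(env, sp), seed = 2)
#' tr <- draw_training(re, env, n_presence = 25, n_background = 200, seed = 3)
#' m <- fit_sdm(tr, "GLM")
#' summary(predict(m, tr))
#' @export
fit_sdm <- function(train,
                    family = c("DOMAIN", "GLM", "MAXENT_LIKE", "RANDOM_FOREST"),
                    ..., seed = 1L) {
  family <- match.arg(family)
  switch(family,
         DOMAIN = fit_domain(train, ...),
         GLM = fit_glm(train, ...),
         MAXENT_LIKE = fit_maxent_like(train, ..., seed = seed),
         RANDOM_FOREST = fit_random_forest(train, ..., seed = seed))
}

covariate_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("covariate matrix must have 3 columns", call. = FALSE)
    m <- points
  } else if (is.data.frame(points)) {
    if (!all(c("x1", "x2", "x3") %in% names(points))) {
      stop("points must carry covariate columns x1, x2, x3", call. = FALSE)
    }
    m <- as.matrix(points[, c("x1", "x2", "x3")])
  } else if (is.numeric(points) && length(points) == 3L) {
    m <- matrix(points, 1L, 3L)
  } else {
    stop("cannot interpret `points` as covariate vectors", call. = FALSE)
  }
  colnames(m) <- c("x1", "x2", "x3")
  m
}

new_sdm_model <- function(family, fit, train, extra = list()) {
  structure(
    c(list(family = family, fit = fit,
           training_ref = list(n_presence = sum(train$label == "presence"),
                               n_background = sum(train$label == "background"),
                               role = train$role[1L])),
      extra),
    class = c(paste0("sdm_", tolower(family)), "sdm_model")
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("Fitted SDM (%s)\n", x$family))
  cat(sprintf("  trained on %d presences, %d background points\n",
              x$training_ref$n_presence, x$training_ref$n_background))
  invisible(x)
}

#' DOMAIN: maximum Gower similarity to training presences
#'
#' Presence-only envelope model. Only the presence points of `train` are
#' used. The Gower distance between a query point q and a presence t is the
#' mean over the three covariates of |q_j - t_j| / range_j, where range_j
#' is the covariate's range over the training presences; the score is
#' 1 minus the minimum distance over presences, clipped to \[0,1\]. A
#' covariate with zero range contributes 0 when the query matches it
#' exactly and the maximal distance 1 otherwise.
#'
#' @inheritParams fit_sdm
#' @return An `sdm_model`.
#' @export
fit_domain <- function(train) {
  pres <- covariate_matrix(train[train$label == "presence", , drop = FALSE])
  if (nrow(pres) < 1L) stop("DOMAIN needs at least one training presence", call. = FALSE)
  ranges <- apply(pres, 2L, function(v) diff(range(v)))
  if (nrow(pres) == 1L) {
    warning("DOMAIN fitted to a single presence: all covariate ranges are zero")
  }
  new_sdm_model("DOMAIN", fit = list(presences = pres, ranges = ranges), train)
}

#' @export
predict.sdm_domain <- function(object, newdata, ...) {
  q <- covariate_matrix(newdata)
  if (nrow(q) == 0L) return(numeric())
  p <- object$fit$presences
  r <- object$fit$ranges
  d <- matrix(0, nrow(q), nrow(p))
  for (j in 1:3) {
    diffs <- abs(outer(q[, j], p[, j], "-"))
    d <- d + if (r[j] > 0) diffs / r[j] else (diffs > 0) * 1
  }
  d <- d / 3
  unname(pmin(pmax(1 - apply(d, 1L, min), 0), 1))
}

#' Logistic regression of presence versus background
#'
#' Maximum-likelihood binomial GLM on the three covariates. If the fit is
#' perfectly separated (fitted probabilities saturate or coefficients
#' diverge), a ridge-penalized logistic fit takes over with a warning so
#' that small training sets never derail a simulation run.
#'
#' @inheritParams fit_sdm
#' @return An `sdm_model`.
#' @export
fit_glm <- function(train) {
  y <- as.integer(train$label == "presence")
  if (length(unique(y)) < 2L) {
    stop("GLM needs both presence and background points", call. = FALSE)
  }
  x <- covariate_matrix(train)
  dat <- data.frame(y = y, x)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x1 + x2 + x3, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # perfect separation can also present as a silently converged fit with
  # essentially zero deviance or runaway coefficients
  if (separated || fit$deviance < 1e-6 || any(abs(stats::coef(fit)) > 25)) {
    warning("perfect separation in GLM training data: falling back to a ridge-penalized fit")
    rfit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.01)
    beta <- as.numeric(stats::coef(rfit))
    return(new_sdm_model("GLM", fit = list(beta = beta, ridge = TRUE), train))
  }
  new_sdm_model("GLM", fit = list(beta = unname(stats::coef(fit)), ridge = FALSE),
                train, extra = list(glm = fit))
}

#' @export
predict.sdm_glm <- function(object, newdata, ...) {
  x <- covariate_matrix(newdata)
  if (nrow(x) == 0L) return(numeric())
  unname(stats::plogis(drop(cbind(1, x) %*% object$fit$beta)))
}

maxent_features <- function(x) {
  cbind(x,
        x1.2 = x[, 1L]^2, x2.2 = x[, 2L]^2, x3.2 = x[, 3L]^2,
        x1x2 = x[, 1L] * x[, 2L],
        x1x3 = x[, 1L] * x[, 3L],
        x2x3 = x[, 2L] * x[, 3L])
}

#' Maxent-like penalized presence-background regression
#'
#' Ridge-penalized logistic regression of presence versus background on
#' linear plus quadratic features of the covariates (squares and pairwise
#' products), mirroring Maxent's regularized exponential-family fit in its
#' presence-background logistic formulation; quadratic features let the
#' response be unimodal in each covariate. The penalty weight is chosen by
#' internal 5-fold cross-validation (deterministic folds derived from
#' `seed`) unless `regularization` is given explicitly. The L2 penalty is
#' deliberate: with a few dozen presences against thousands of background
#' points, an L1 path cross-validates erratically (the selected model is
#' often the empty one), whereas ridge shrinks the score surface smoothly
#' and preserves its ranking even when strongly penalized.
#'
#' @inheritParams fit_sdm
#' @param regularization Nonnegative penalty weight (glmnet lambda), or
#'   `NULL` (default) to choose it by cross-validation. Very large values
#'   shrink the model to a constant score equal to the presence fraction of
#'   the training table.
#' @return An `sdm_model`.
#' @export
fit_maxent_like <- function(train, regularization = NULL, seed = 1L) {
  y <- as.integer(train$label == "presence")
  if (length(unique(y)) < 2L) {
    stop("MAXENT_LIKE needs both presence and background points", call. = FALSE)
  }
  x <- maxent_features(covariate_matrix(train))
  if (is.null(regularization)) {
    foldid <- with_seed(seed, sample(rep_len(1:5, length(y))))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                            foldid = foldid, nfolds = 5)
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  } else {
    if (regularization < 0) stop("`regularization` must be nonnegative", call. = FALSE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = regularization)
    lambda <- regularization
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))
  new_sdm_model("MAXENT_LIKE", fit = list(beta = beta, lambda = lambda), train)
}

#' @export
predict.sdm_maxent_like <- function(object, newdata, ...) {
  x <- maxent_features(covariate_matrix(newdata))
  if (nrow(x) == 0L) return(numeric())
  unname(stats::plogis(drop(cbind(1, x) %*% object$fit$beta)))
}

#' Random Forest of presence versus background
#'
#' Classification forest via the randomForest package; a site's score is
#' the fraction of trees voting presence. Training follows the 2:1
#' background:presence design (background-heavy tables degrade forest
#' accuracy). Fully seeded: the same seed gives an identical forest.
#'
#' @inheritParams fit_sdm
#' @param n_trees Number of trees.
#' @return An `sdm_model`.
#' @export
fit_random_forest <- function(train, n_trees = 500L, seed = 1L) {
  if (nrow(train) < 10L) {
    stop("RANDOM_FOREST needs at least 10 training points", call. = FALSE)
  }
  y <- factor(ifelse(train$label == "presence", "pres", "bg"),
              levels = c("bg", "pres"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("RANDOM_FOREST needs both presence and background points", call. = FALSE)
  }
  x <- covariate_matrix(train)
  forest <- with_seed(seed, randomForest::randomForest(x, y, ntree = n_trees))
  new_sdm_model("RANDOM_FOREST", fit = list(forest = forest, n_trees = n_trees),
                train)
}

#' @export
predict.sdm_random_forest <- function(object, newdata, ...) {
  x <- covariate_matrix(newdata)
  if (nrow(x) == 0L) return(numeric())
  unname(stats::predict(object$fit$forest, x, type = "prob")[, "pres"])
}

#' Score a sample set with a fitted model
#'
#' Applies the model's score contract to every point of `points`,
#' preserving labels and role. Scoring the training set itself is
#' permitted (and used by in-sample diagnostics).
#'
#' @param model An `sdm_model`.
#' @param points A `sample_set`.
#' @return A `scored_set`: the input data frame plus a `score` column in
#'   \[0,1\].
#' @export
score_set <- function(model, points) {
  stopifnot(inherits(model, "sdm_model"), is.data.frame(points))
  s <- if (nrow(points) == 0L) numeric() else predict(model, points)
  if (length(s) && (min(s) < -1e-8 || max(s) > 1 + 1e-8)) {
    stop("model emitted scores outside [0, 1]", call. = FALSE)
  }
  points$score <- pmin(pmax(s, 0), 1)
  class(points) <- unique(c("scored_set", class(points)))
  points
}
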