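test_that("DOMAIN scores follow the Gower similarity closed form", {
  tr <- make_set(rbind(c(0, 0, 0), c(1, 1, 1)),
                 label = c("presence", "presence"))
  m <- fit_domain(tr)

  expect_equal(predict(m, c(0, 0, 0)), 1)      # exact match dominates the max
  expect_equal(predict(m, c(1, 1, 1)), 1)
  expect_equal(predict(m, c(0.5, 0.5, 0.5)), 0.5)  # distance 0.5 to both
  expect_equal(predict(m, c(5, 5, 5)), 0)      # Gower distance > 1 clipped

  # asymmetric query: distances (0.2+0.3+0.1)/3 = 0.2 vs (0.8+0.7+0.9)/3 = 0.8
  expect_equal(predict(m, c(0.2, 0.3, 0.1)), 0.8)
})

test_that("DOMAIN handles zero-range covariates by the exact-match rule", {
  tr <- make_set(rbind(c(0, 0, 2), c(1, 1, 2)),
                 label = c("presence", "presence"))
  m <- fit_domain(tr)
  # matching the constant covariate: its term is 0
  expect_equal(predict(m, c(0, 0, 2)), 1)
  # mismatching it contributes maximal distance 1 on that covariate
  expect_equal(predict(m, c(0, 0, 3)), 1 - 1 / 3)

  expect_warning(fit_domain(make_set(c(1, 2, 3), "presence")), "single presence")
})

test_that("DOMAIN is invariant under per-covariate affine rescaling", {
  set.seed(77)
  pres <- matrix(rnorm(30), 10, 3)
  qry <- matrix(rnorm(15), 5, 3)
  m <- fit_domain(make_set(pres, rep("presence", 10)))
  base <- predict(m, qry)

  a <- c(2.5, 0.3, 10); b <- c(-1, 4, 0.2)
  resc <- function(x) sweep(sweep(x, 2, a, "*"), 2, b, "+")
  m2 <- fit_domain(make_set(resc(pres), rep("presence", 10)))
  expect_equal(predict(m2, resc(qry)), base, tolerance = 1e-12)
})

test_that("GLM recovers generating coefficients from pa-style data", {
  set.seed(5)
  x <- matrix(rnorm(5000 * 3), 5000, 3)
  beta <- c(-0.5, 1.2, -0.8, 0.6)
  y <- rbinom(5000, 1, plogis(beta[1] + x %*% beta[2:4]))
  tr <- make_set(x, ifelse(y == 1, "presence", "background"))
  m <- fit_glm(tr)
  expect_lt(max(abs(m$fit$beta - beta)), 0.2)
  expect_gt(m$fit$beta[2], 0)  # sign matches the generating geometry
})

test_that("GLM on permuted labels is a null model", {
  set.seed(6)
  x <- matrix(rnorm(2000 * 3), 2000, 3)
  tr <- make_set(x, sample(rep(c("presence", "background"), c(400, 1600))))
  m <- fit_glm(tr)
  sc <- score_set(m, tr)
  expect_lt(abs(auc(sc) - 0.5), 0.05)
})

test_that("GLM falls back to a ridge fit under perfect separation", {
  x <- rbind(cbind(rnorm(20, 3, 0.1), rnorm(20), rnorm(20)),
             cbind(rnorm(40, -3, 0.1), rnorm(40), rnorm(40)))
  tr <- make_set(x, rep(c("presence", "background"), c(20, 40)))
  expect_warning(m <- fit_glm(tr), "separation")
  s <- predict(m, x)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(mean(s[1:20]), mean(s[21:60]))  # still discriminates
})

test_that("Maxent-like quadratic features capture a unimodal response", {
  set.seed(7)
  pres <- cbind(rnorm(120, 0, 0.4), rnorm(120), rnorm(120))
  bg <- cbind(runif(1200, -3, 3), rnorm(1200), rnorm(1200))
  tr <- make_set(rbind(pres, bg),
                 rep(c("presence", "background"), c(120, 1200)))
  m <- fit_maxent_like(tr, seed = 1)
  expect_lt(m$fit$beta[5], 0)  # coefficient on x1^2 is negative at a peak
})

test_that("Maxent-like fits are deterministic and shrink to a constant", {
  set.seed(8)
  x <- matrix(rnorm(600), 200, 3)
  lab <- rep(c("presence", "background"), c(40, 160))
  tr <- make_set(x, lab)
  m1 <- fit_maxent_like(tr, seed = 42)
  m2 <- fit_maxent_like(tr, seed = 42)
  expect_identical(m1$fit$beta, m2$fit$beta)

  heavy <- fit_maxent_like(tr, regularization = 1e4)
  s <- predict(heavy, x)
  expect_lt(diff(range(s)), 1e-3)
  expect_equal(mean(s), 0.2, tolerance = 0.01)  # presence fraction of the table
})

test_that("Random Forest votes behave as probability scores", {
  set.seed(9)
  x <- matrix(rnorm(90), 30, 3)
  lab <- rep(c("presence", "background"), c(10, 20))
  tr <- make_set(x, lab)

  m1 <- fit_random_forest(tr, n_trees = 1, seed = 3)
  s1 <- predict(m1, x)
  expect_true(all(s1 %in% c(0, 1)))

  ma <- fit_random_forest(tr, seed = 4)
  mb <- fit_random_forest(tr, seed = 4)
  expect_identical(predict(ma, x), predict(mb, x))

  # training presences score higher than background on average (in-bag memory)
  s <- predict(ma, x)
  expect_gt(mean(s[1:10]), mean(s[11:30]))

  expect_error(fit_random_forest(make_set(rnorm(9), rep(c("presence", "background"), c(1, 2))), seed = 1),
               "at least 10")
})

test_that("all backends emit scores in [0, 1] through score_set", {
  env <- generate_environment(40, 40, seed = 31)
  sp <- species_definition(c(calibrate_intercept(env, c(1.5, -0.9, 0.5), 0.3),
                             1.5, -0.9, 0.5))
  re <- realize(suitability(env, sp), seed = 32)
  tr <- draw_training(re, env, 25, 200, seed = 33)
  tr_rf <- draw_training(re, env, 25, 50, seed = 34)
  te <- draw_test(re, env, list(tr, tr_rf), total = 200, seed = 35)

  for (fam in c("DOMAIN", "GLM", "MAXENT_LIKE", "RANDOM_FOREST")) {
    m <- fit_sdm(if (fam == "RANDOM_FOREST") tr_rf else tr, fam, seed = 36)
    sc <- score_set(m, te)
    expect_true(all(sc$score >= 0 & sc$score <= 1), info = fam)
    expect_identical(nrow(sc), nrow(te))
    expect_identical(sc$label, te$label)
    # scoring the training set itself is part of the contract
    sc_tr <- score_set(m, tr)
    expect_true(all(sc_tr$score >= 0 & sc_tr$score <= 1), info = fam)
  }
})

test_that("GLM test AUC clears the qualitative floor for well-separated species", {
  env <- generate_environment(100, 100, seed = 41)
  for (i in 1:3) {
    sl <- default_species_slopes(6)[i, ]
    sp <- species_definition(c(calibrate_intercept(env, sl, 0.3), sl))
    re <- realize(suitability(env, sp), seed = 50 + i)
    tr <- draw_training(re, env, 50, 1000, seed = 60 + i)
    te <- draw_test(re, env, tr, total = 1000, seed = 70 + i)
    m <- fit_glm(tr)
    expect_gt(auc(score_set(m, te)), 0.75)
  }
})

test_that("empty and malformed inputs are rejected cleanly", {
  tr <- make_set(matrix(rnorm(30), 10, 3), rep(c("presence", "background"), 5))
  m <- fit_glm(tr)
  expect_length(predict(m, tr[0, ]), 0)
  expect_error(predict(m, matrix(1, 2, 2)), "3 columns")
  expect_error(fit_glm(make_set(rnorm(3), "presence")), "both presence and background")
})
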