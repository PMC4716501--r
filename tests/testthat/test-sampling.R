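# One moderately occupied realization shared across sampling tests.
sampling_fixture <- local({
  env <- generate_environment(100, 100, seed = 101)
  sp <- species_definition(c(calibrate_intercept(env, c(1, -0.8, 0.5), 0.3),
                             1, -0.8, 0.5))
  re <- realize(suitability(env, sp), seed = 102)
  list(env = env, re = re)
})

test_that("training draws have the required composition and provenance", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  tr <- draw_training(re, env, n_presence = 50, n_background = 5000, seed = 1)
  expect_identical(sum(tr$label == "presence"), 50L)
  expect_identical(sum(tr$label == "background"), 5000L)
  expect_equal(attr(tr, "kp_rp_ratio"), 0.01)

  pres_cells <- tr$cell_id[tr$label == "presence"]
  expect_true(all(re$occupancy[pres_cells] == 1L))
  expect_false(any(duplicated(pres_cells)))
  expect_false(any(duplicated(tr$cell_id[tr$label == "background"])))

  rf <- draw_training(re, env, n_presence = 50, n_background = 100, seed = 2)
  expect_equal(attr(rf, "kp_rp_ratio"), 0.5)

  expect_identical(draw_training(re, env, 50, 500, seed = 3)$cell_id,
                   draw_training(re, env, 50, 500, seed = 3)$cell_id)
  expect_error(draw_training(re, env, n_presence = 0), "at least 1")
  expect_error(draw_training(re, env, n_presence = env$n_cells),
               "realized prevalence")
})

test_that("test sets follow the prevalence-proportional composition rule", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  tr <- draw_training(re, env, 50, 1000, seed = 4)
  te <- draw_test(re, env, tr, total = 3000, seed = 5)

  n1 <- round(3000 * re$realized_prevalence)
  expect_identical(sum(te$label == "presence"), as.integer(n1))
  expect_identical(nrow(te), 3000L)
  expect_true(all(re$occupancy[te$cell_id[te$label == "presence"]] == 1L))
  expect_true(all(re$occupancy[te$cell_id[te$label == "absence"]] == 0L))
  expect_length(intersect(te$cell_id, tr$cell_id), 0)

  half <- realize(rep(0.5, 10000), seed = 6)
  te50 <- draw_test(half, env, NULL, total = 3000, seed = 7)
  expect_identical(sum(te50$label == "presence"),
                   as.integer(round(3000 * half$realized_prevalence)))
})

test_that("presence-only validation sets exclude train/test presences but draw background from the full grid", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  tr <- draw_training(re, env, 50, 5000, seed = 8)
  te <- draw_test(re, env, tr, total = 3000, seed = 9)

  po1 <- draw_validation_po(re, env, tr, te, n1val = 50, nrpval = 5000,
                            seed = 10, role = "po1")
  expect_equal(attr(po1, "kp_rp_ratio"), 0.01)
  po_pres <- po1$cell_id[po1$label == "presence"]
  expect_length(intersect(po_pres, tr$cell_id), 0)
  expect_length(intersect(po_pres, te$cell_id), 0)
  expect_true(all(re$occupancy[po_pres] == 1L))

  po4 <- draw_validation_po(re, env, tr, te, 500, 5, seed = 11, role = "po4")
  expect_equal(attr(po4, "kp_rp_ratio"), 100)

  expect_error(draw_validation_po(re, env, tr, te, 50, 0), "at least 1")
  expect_error(draw_validation_po(re, env, tr, te, env$n_cells, 50),
               "insufficient presences")
})

test_that("background points are occupied at the prevalence rate", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  pi_hat <- re$realized_prevalence
  po <- draw_validation_po(re, env, NULL, NULL, 50, 5000, seed = 12)
  bg <- po$cell_id[po$label == "background"]
  s_emp <- mean(re$occupancy[bg])
  expect_lt(abs(s_emp - pi_hat), 3 * sqrt(pi_hat * (1 - pi_hat) / 5000))
})

test_that("pa validation sets respect both exclusions and the composition rule", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  tr <- draw_training(re, env, 50, 500, seed = 13)
  te <- draw_test(re, env, tr, total = 1000, seed = 14)
  pa <- draw_validation_pa(re, env, tr, te, total = 5000, seed = 15)

  expect_identical(pa$role[1], "pa1")
  expect_identical(sum(pa$label == "presence"),
                   as.integer(round(5000 * re$realized_prevalence)))
  expect_length(intersect(pa$cell_id, c(tr$cell_id, te$cell_id)), 0)
  expect_true(all(re$occupancy[pa$cell_id[pa$label == "presence"]] == 1L))
  expect_true(all(re$occupancy[pa$cell_id[pa$label == "absence"]] == 0L))
})

test_that("sample sets round-trip through CSV", {
  env <- sampling_fixture$env; re <- sampling_fixture$re
  tr <- draw_training(re, env, 25, 100, seed = 16)
  path <- tempfile(fileext = ".csv")
  write_sample_set(tr, path)
  back <- read_sample_set(path)
  expect_equal(back$cell_id, tr$cell_id)
  expect_equal(back$label, tr$label)
  expect_equal(attr(back, "kp_rp_ratio"), attr(tr, "kp_rp_ratio"))
})
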