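test_that("confusion metrics match hand-computed values", {
  perfect <- confusion_counts(10, 0, 0, 10)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(tss(perfect), 1)
  expect_equal(f_measure(perfect), 1)

  symmetric <- confusion_counts(5, 5, 5, 5)
  expect_equal(sensitivity(symmetric), 0.5)
  expect_equal(specificity(symmetric), 0.5)
  expect_equal(tss(symmetric), 0)
  expect_equal(f_measure(symmetric), 0.5)

  cc <- confusion_counts(8, 2, 4, 86)
  expect_equal(f_measure(cc), 2 * (2 / 3) * 0.8 / ((2 / 3) + 0.8))
  expect_equal(f_measure(cc), 0.72727, tolerance = 1e-5)

  nothing_present <- confusion_counts(0, 10, 0, 90)
  expect_true(is.na(f_measure(nothing_present)))
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("F_pb matches hand-computed values and can exceed 1", {
  expect_equal(f_pb(confusion_counts(10, 0, 10, 0)), 1)
  cc <- confusion_counts(8, 2, 4, 6)
  expect_equal(f_pb(cc), 2 * 2 * 0.8 / 2.8)
  expect_gt(f_pb(cc), 1)
  expect_equal(f_pb(confusion_counts(0, 5, 3, 7)), 0)
  # no predicted presences among background: limit 2 * recall
  expect_equal(f_pb(confusion_counts(6, 2, 0, 10)), 2 * 0.75)
})

test_that("presence-only identities hold over their whole parameter range", {
  expect_equal(sss_identity(0, 1.6), 1.6)
  expect_equal(tss_identity(0, 0.6), 0.6)
  expect_equal(sss_identity(1, 1.6), 1)
  expect_equal(tss_identity(1, 0.6), 0)
  expect_equal(sss_identity(0.25, 1.6), 1.45)
  expect_error(sss_identity(1.5, 1), "\\[0, 1\\]")
})

test_that("F_pb as a function of c reproduces its limits", {
  expect_equal(fpb_from_precision_recall(0.3, 0.7, 1),
               2 * 0.3 * 0.7 / (0.3 + 0.7))
  expect_equal(fpb_from_precision_recall(0.5, 0.5, 1e9), 2 * 0.5, tolerance = 1e-8)
  expect_equal(fpb_from_precision_recall(0.6, 0.9, 0.5), 0.45)

  cr <- c_ratio(n1 = 50, n0 = 5000, prevalence = 0.01)
  expect_equal(cr$c, 1)
  expect_equal(fpb_from_precision_recall(0.2, 0.4, cr),
               2 * 0.2 * 0.4 / 0.6)
})

test_that("threshold scans match brute-force confusion counts", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), sample(c(1, 2), 1))  # force ties sometimes
    labels <- sample(c("presence", "absence"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sc <- make_scored(scores, labels)
    scan <- threshold_scan(sc)
    for (i in seq_len(nrow(scan$table))) {
      expected <- oracle_counts(scores, labels, scan$table$threshold[i])
      got <- unlist(scan$table[i, c("tp", "fn", "fp", "tn")])
      expect_identical(unname(got), unname(expected))
    }
  }
})

test_that("scan sentinels cover the all-present and none-present extremes", {
  sc <- make_scored(c(0.2, 0.8), c("absence", "presence"))
  scan <- threshold_scan(sc)
  tab <- scan$table
  expect_equal(tab$Se[1], 1)   # below-min: everything predicted present
  expect_equal(tab$Sp[1], 0)
  expect_equal(tab$Se[nrow(tab)], 0)  # above-max: nothing predicted present
  expect_equal(tab$Sp[nrow(tab)], 1)
  # at 0.5 the pair separates perfectly
  mid <- tab[tab$threshold == 0.8, ]
  expect_identical(unname(unlist(mid[c("tp", "fn", "fp", "tn")])), c(1L, 0L, 0L, 1L))
  expect_error(threshold_scan(make_scored(c(0.1, 0.2), c("presence", "presence"))),
               "at least one")
})

test_that("grid scans agree with exhaustive enumeration on a toy set", {
  scores <- c(0.05, 0.15, 0.42, 0.55, 0.58, 0.91)
  labels <- c("absence", "absence", "presence", "absence", "presence", "presence")
  scan <- threshold_scan(make_scored(scores, labels),
                         candidate_rule = "grid", step = 0.1)
  for (i in seq_len(nrow(scan$table))) {
    expected <- oracle_counts(scores, labels, scan$table$threshold[i])
    got <- unlist(scan$table[i, c("tp", "fn", "fp", "tn")])
    expect_identical(unname(got), unname(expected))
  }
})

test_that("select_threshold agrees with the exhaustive oracle", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), sample(1:3, 1))
    kind <- sample(c("pa", "po"), 1)
    other <- if (kind == "pa") "absence" else "background"
    labels <- sample(c("presence", other), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sc <- make_scored(scores, labels)
    scan <- threshold_scan(sc)
    crits <- if (kind == "pa") c("maxSSS", "maxF") else c("maxSSS", "maxFpb")
    for (cr in crits) {
      got <- select_threshold(scan, cr)
      want <- oracle_select(scores, labels, cr)
      expect_equal(got$value, want$value, tolerance = 1e-12)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    }
  }
})

test_that("exact criterion ties break toward the smallest threshold", {
  scores <- c(0.9, 0.5, 0.7, 0.1)
  labels <- c("presence", "presence", "absence", "absence")
  scan <- threshold_scan(make_scored(scores, labels))
  ch <- select_threshold(scan, "maxSSS")
  # SSS = 1.5 at both 0.5 and 0.9; the smaller wins
  expect_equal(ch$threshold, 0.5)
  expect_equal(ch$value, 1.5)
})

test_that("criterion/data-kind compatibility is enforced", {
  pa <- threshold_scan(make_scored(c(0.2, 0.8), c("absence", "presence")))
  po <- threshold_scan(make_scored(c(0.2, 0.8), c("background", "presence")))
  expect_error(select_threshold(pa, "maxFpb"), "presence-only")
  expect_error(select_threshold(po, "maxF"), "presence/absence")
  expect_equal(select_threshold(pa, "maxSSS")$value, 2)  # separable pair
  expect_equal(select_threshold(po, "maxSSS")$value, 2)
})

test_that("planting the pa set as its own background makes the SSS identity exact", {
  set.seed(17)
  n1 <- 40; n0 <- 60
  scores_p <- runif(n1, 0.3, 1)
  scores_a <- runif(n0, 0, 0.7)
  pa <- make_scored(c(scores_p, scores_a),
                    rep(c("presence", "absence"), c(n1, n0)))
  # background = the entire pa set, so the contamination is exactly s
  s <- n1 / (n1 + n0)
  po <- make_scored(c(scores_p, scores_p, scores_a),
                    rep(c("presence", "background"), c(n1, n1 + n0)))

  scan_pa <- threshold_scan(pa)
  scan_po <- threshold_scan(po)
  common <- intersect(scan_pa$table$threshold, scan_po$table$threshold)
  for (t in common) {
    sss_pa <- scan_pa$table$SSS[scan_pa$table$threshold == t]
    sss_po <- scan_po$table$SSS[scan_po$table$threshold == t]
    expect_equal(sss_po, sss_identity(s, sss_pa), tolerance = 1e-12)
    tss_pa <- scan_pa$table$TSS[scan_pa$table$threshold == t]
    tss_po <- scan_po$table$TSS[scan_po$table$threshold == t]
    expect_equal(tss_po, tss_identity(s, tss_pa), tolerance = 1e-12)
  }
  # and therefore the maxSSS argmax is identical on both data kinds
  expect_equal(select_threshold(scan_po, "maxSSS")$threshold,
               select_threshold(scan_pa, "maxSSS")$threshold)
})

test_that("scan tables export to CSV", {
  scan <- threshold_scan(make_scored(c(0.2, 0.5, 0.8),
                                     c("absence", "presence", "presence")))
  path <- tempfile(fileext = ".csv")
  write_threshold_scan(scan, path)
  back <- read.csv(path)
  expect_equal(back$threshold, scan$table$threshold)
  expect_equal(back$Fpb, scan$table$Fpb)
})
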