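test_that("confusion counts and row percentages are exact", {
  s <- stage_sequence(c("W", "L", "D", "R", "W"))
  cm <- confusion(s, s)
  expect_equal(sum(diag(cm$counts)), 5)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)

  # random pair vs hand-counted tallies
  set.seed(14)
  ref <- stage_sequence(sample(stage_codes(), 20, replace = TRUE))
  est <- stage_sequence(sample(stage_codes(), 20, replace = TRUE))
  cm <- confusion(ref, est)
  for (i in stage_codes()) for (j in stage_codes())
    expect_equal(cm$counts[i, j],
                 sum(ref$labels == i & est$labels == j))

  expect_error(confusion(ref, stage_sequence("W")), "length mismatch")
})

test_that("Cohen's kappa matches its definition", {
  s <- stage_sequence(c("W", "L", "D", "R"))
  expect_equal(cohens_kappa(confusion(s, s)), 1.0)

  cm <- confusion_from_counts(matrix(c(45, 15, 25, 15), 2, 2, byrow = TRUE))
  expect_equal(cohens_kappa(cm), 0.06 / 0.46, tolerance = 1e-12)

  # independent shuffles sit at chance level
  set.seed(15)
  a <- sample(stage_codes(), 40000, replace = TRUE)
  b <- sample(stage_codes(), 40000, replace = TRUE)
  k <- cohens_kappa(confusion(stage_sequence(a), stage_sequence(b)))
  expect_lt(abs(k), 0.02)

  # degenerate single-class agreement is flagged
  cm1 <- confusion_from_counts(matrix(c(10, 0, 0, 0), 2, 2))
  k1 <- cohens_kappa(cm1)
  expect_equal(as.numeric(k1), 1)
  expect_true(isTRUE(attr(k1, "degenerate")))
})

test_that("binary metrics handle undefined denominators", {
  cm <- confusion_from_counts(matrix(c(8, 2, 5, 85), 2, 2, byrow = TRUE,
                                     dimnames = list(c("pos", "neg"),
                                                     c("pos", "neg"))))
  bm <- binary_metrics(cm, "pos")
  expect_equal(unname(bm["sensitivity"]), 80.0)
  expect_equal(unname(bm["specificity"]), 85 / 90 * 100, tolerance = 1e-9)
  expect_equal(unname(bm["ppv"]), 8 / 13 * 100, tolerance = 1e-9)

  cm0 <- confusion_from_counts(matrix(c(0, 0, 5, 95), 2, 2, byrow = TRUE,
                                      dimnames = list(c("pos", "neg"),
                                                      c("pos", "neg"))))
  expect_true(is.na(binary_metrics(cm0, "pos")["sensitivity"]))

  cmp <- confusion_from_counts(diag(c(10, 90)))
  rownames(cmp$counts) <- colnames(cmp$counts) <- c("pos", "neg")
  expect_equal(unname(binary_metrics(cmp, "pos")), c(100, 100, 100, 100))
})

test_that("cohort summaries pick the presentation by normality", {
  v <- (1:100) / 100
  cs <- cohort_summary(v)
  expect_identical(cs$primary, "median_iqr")
  expect_equal(cs$median, 0.505)

  # quartiles match a sorted-rank interpolation done by hand
  set.seed(16)
  w <- rnorm(37)
  cs <- cohort_summary(w)
  sw <- sort(w)
  h <- function(p) {
    r <- (length(sw) - 1) * p + 1
    lo <- floor(r)
    sw[lo] + (r - lo) * (sw[min(lo + 1, length(sw))] - sw[lo])
  }
  expect_equal(cs$q1, h(0.25), tolerance = 1e-12)
  expect_equal(cs$q3, h(0.75), tolerance = 1e-12)

  cs <- cohort_summary(rep(3.2, 5))
  expect_equal(cs$median, 3.2)
  expect_equal(cs$mean, 3.2)
  expect_equal(cs$q3 - cs$q1, 0)

  expect_error(cohort_summary(c(1, 2)), "at least 3")
})

test_that("sleep metrics match a hand-counted toy hypnogram", {
  hyp <- stage_sequence(c("W", "W", "L", "L", "R", "W", "D", "D"))
  m <- sleep_metrics(hyp)
  expect_equal(m$tst_min, 2.5)
  expect_equal(m$sleep_latency_min, 1.0)
  expect_equal(m$waso_min, 0.5)
  expect_equal(m$r_latency_min, 1.0)
  expect_equal(m$sleep_efficiency_pct, 62.5)
  expect_equal(m$time_n3_min, 1.0)
  # conservation: stage times sum to the recording, sleep stages to TST
  expect_equal(m$time_wake_min + m$time_n12_min + m$time_n3_min +
                 m$time_rem_min, 4.0)
  expect_equal(m$time_n12_min + m$time_n3_min + m$time_rem_min, m$tst_min)

  mw <- sleep_metrics(stage_sequence(rep("W", 10)))
  expect_equal(mw$tst_min, 0)
  expect_equal(mw$sleep_efficiency_pct, 0)
  expect_true(is.na(mw$sleep_latency_min))

  ml <- sleep_metrics(stage_sequence(rep("L", 10)))
  expect_equal(ml$tst_min, 5)
  expect_equal(ml$sleep_efficiency_pct, 100)
})

test_that("Bland-Altman limits use the sample SD of errors", {
  x <- c(10, 20, 30)
  ba <- bland_altman(x, x)
  expect_equal(ba$median, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)

  ba <- bland_altman(c(8, 20, 32), c(10, 20, 30))
  expect_equal(ba$median, 0)
  expect_equal(ba$loa_lower, -1.96 * 2, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.96 * 2, tolerance = 1e-12)

  set.seed(17)
  ba <- bland_altman(rnorm(20), rnorm(20))
  expect_lte(ba$loa_lower, ba$loa_upper)
})

test_that("gap-tolerant intervals merge runs up to M epochs apart", {
  lab <- rep("W", 10)
  lab[c(1, 2, 5, 9)] <- "R"
  hyp <- stage_sequence(lab)
  iv2 <- stage_intervals(hyp, "R", M = 2)$intervals
  expect_equal(unname(iv2), matrix(c(1L, 5L, 9L, 9L), 2, 2, byrow = TRUE))
  iv0 <- stage_intervals(hyp, "R", M = 0)$intervals
  expect_equal(unname(iv0), matrix(c(1L, 2L, 5L, 5L, 9L, 9L), 3, 2,
                                   byrow = TRUE))
  expect_equal(nrow(stage_intervals(hyp, "D", M = 2)$intervals), 0)
})

test_that("interval matching counts overlaps with earliest-first ties", {
  lab <- rep("W", 30); lab[c(1:5, 9)] <- "R"
  ref <- stage_intervals(stage_sequence(lab), "R", 0)
  expect_equal(nrow(ref$intervals), 2)
  mm <- match_intervals(ref, ref)
  expect_equal(mm$n_ref_matched, mm$n_ref)
  expect_length(mm$unmatched_est, 0)

  mk_iv <- function(iv) structure(list(stage = "R", M = 0,
                                       intervals = iv, n_epochs = 40),
                                  class = "stage_interval_set")
  a <- mk_iv(matrix(c(10L, 20L), 1, 2, dimnames = list(NULL, c("start", "end"))))
  b <- mk_iv(matrix(c(21L, 30L), 1, 2, dimnames = list(NULL, c("start", "end"))))
  mm <- match_intervals(a, b)
  expect_equal(mm$n_ref_matched, 0)
  expect_equal(mm$unmatched_est, 1L)

  r2 <- mk_iv(matrix(c(1L, 5L, 9L, 9L), 2, 2, byrow = TRUE,
                     dimnames = list(NULL, c("start", "end"))))
  e2 <- mk_iv(matrix(c(4L, 6L), 1, 2, dimnames = list(NULL, c("start", "end"))))
  mm <- match_intervals(r2, e2)
  expect_equal(mm$n_ref_matched, 1)
  expect_equal(mm$unmatched_ref, 2L)
  expect_equal(unname(mm$pairs[1, 1:2]), c(1, 1))
})

test_that("factor influence runs the full testing battery", {
  kap <- c(1, 2, 3, 4, 5, 6) / 10
  res <- factor_influence(kap,
                          binary_factors = list(grp = c(TRUE, TRUE, TRUE,
                                                        FALSE, FALSE, FALSE)),
                          continuous_factors = list(age = 1:6))
  expect_equal(res$p[res$factor == "grp"], 0.1, tolerance = 1e-12)
  expect_equal(res$statistic[res$factor == "age"], 1.0)

  expect_warning(
    r2 <- factor_influence(kap, binary_factors = list(all = rep(TRUE, 6))),
    "empty group")
  expect_equal(nrow(r2), 0)
})
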