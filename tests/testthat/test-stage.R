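make_toy_bundle <- function(n_epochs, ihr = 60, res_hz = 0.25) {
  n <- n_epochs * 300
  tt <- (seq_len(n) - 1) / 10
  effort_bundle(
    ihr = gapped_series(rep(ihr, n), 10),
    res = gapped_series(sin(2 * pi * res_hz * tt), 10),
    act = rep(0, n), act1hz = rep(0, n / 10),
    resact = gapped_series(sin(2 * pi * res_hz * tt), 10))
}

test_that("epoch features capture level, variability and spectra", {
  b <- make_toy_bundle(4)
  f <- epochize(b)
  expect_equal(nrow(f), 4)
  expect_equal(f$ihr_mean, rep(60, 4))
  expect_equal(f$ihr_sd, rep(0, 4))
  expect_equal(f$ihr_sdsd, rep(0, 4))
  expect_true(all(abs(f$resp_f - 0.25) <= 0.02))
  expect_false(any(f$missing))

  # boundary: one sample short of 61 epochs gives 60 feature rows
  b61 <- make_toy_bundle(61)
  trim <- function(g, n) gapped_series(g$values[1:n], 10, valid = g$valid[1:n])
  n <- 61 * 300 - 1
  b60 <- effort_bundle(trim(b61$ihr, n), trim(b61$res, n),
                       b61$act[1:n], b61$act1hz, trim(b61$resact, n))
  expect_equal(nrow(epochize(b60)), 60)

  # low-validity epochs are flagged missing
  v <- rep(TRUE, 4 * 300); v[301:600] <- FALSE
  bm <- make_toy_bundle(4)
  bm$ihr$valid <- v
  fm <- epochize(bm)
  expect_identical(fm$missing, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(fm$ihr_mean[2]))
})

test_that("training fits a separable rule and is deterministic", {
  set.seed(33)
  n <- 400
  mk <- function(seed) {
    set.seed(seed)
    lab <- sample(stage_codes(), n, replace = TRUE)
    f <- as.data.frame(matrix(rnorm(n * 24, 0, 0.1), n, 24,
                              dimnames = list(NULL, accelsleep:::epoch_feature_names())))
    # one feature linearly separates the classes
    f$ihr_mean <- c(W = 80, L = 60, D = 40, R = 100)[lab] + rnorm(n, 0, 1)
    f$missing <- FALSE
    list(f = f, s = stage_sequence(lab))
  }
  r1 <- mk(1); r2 <- mk(2)
  m <- train_stager(list(r1$f, r2$f), list(r1$s, r2$s), seed = 5)
  est <- classify_stages(r1$f, m)
  expect_gt(mean(est$labels == r1$s$labels), 0.99)

  m2 <- train_stager(list(r1$f, r2$f), list(r1$s, r2$s), seed = 5)
  expect_identical(m$coef, m2$coef)
  expect_identical(m$transition, m2$transition)

  expect_error(train_stager(list(r1$f), list(r1$s), seed = 1), "at least 2")
  rW <- r1; rW$s <- stage_sequence(rep("L", n)); rW$f$ihr_mean <- rnorm(n, 60)
  expect_error(train_stager(list(rW$f, rW$f), list(rW$s, rW$s), seed = 1),
               "W")
})

test_that("decoding honors temporal context and normalization", {
  # uniform emissions with near-identity transitions and Wake-certain
  # start keep the whole path in Wake
  n <- 10
  logem <- matrix(0, n, 4)
  trans <- matrix(0.01, 4, 4)
  diag(trans) <- 0.97
  init <- c(1 - 3e-9, 1e-9, 1e-9, 1e-9)
  path <- viterbi_path(logem, trans, init)
  expect_identical(path, rep(1L, n))

  # posteriors are proper distributions
  set.seed(71)
  post <- smooth_posteriors(matrix(rnorm(24), 6, 4), trans, rep(0.25, 4))
  expect_equal(rowSums(post), rep(1, 6), tolerance = 1e-9)

  # exact agreement with exhaustive path enumeration on toy instances
  set.seed(77)
  for (rep_i in 1:5) {
    logem <- matrix(log(runif(6 * 4)), 6, 4)
    tm <- matrix(runif(16) + 0.05, 4, 4)
    tm <- tm / rowSums(tm)
    init <- runif(4) + 0.05; init <- init / sum(init)
    expect_identical(viterbi_path(logem, tm, init),
                     as.integer(oracle_viterbi(logem, tm, init)))
  }
})

test_that("class merging follows the NREM and one-vs-rest schemes", {
  s <- stage_sequence(c("L", "D", "R", "W"))
  m3 <- merge_classes(s, "three")
  expect_identical(m3$labels, c("N", "N", "R", "W"))

  mb <- merge_classes(stage_sequence(c("W", "D")), "one_vs_rest",
                      positive = "W")
  expect_identical(mb$labels, c("pos", "neg"))

  # merged probabilities remain distributions
  p <- matrix(c(0.4, 0.3, 0.2, 0.1,
                0.1, 0.2, 0.3, 0.4), 2, 4, byrow = TRUE,
              dimnames = list(NULL, stage_codes()))
  s <- stage_sequence(c("W", "R"), probs = p)
  m3 <- merge_classes(s, "three")
  expect_equal(rowSums(m3$probs), c(1, 1))
  expect_equal(unname(m3$probs[1, "N"]), 0.5)

  expect_error(merge_classes(m3, "three"), "four-class")
})
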