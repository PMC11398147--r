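test_that("channel collapse is the arithmetic sum", {
  a <- triaxial_accel(c(1, 2), c(3, 4), c(5, 6), fs = 100)
  expect_equal(collapse_channels(a), c(9, 12))
  z <- triaxial_accel(numeric(4), numeric(4), numeric(4), fs = 100)
  expect_equal(collapse_channels(z), numeric(4))
})

test_that("activity counts implement the per-second MAD formula", {
  # constant channels carry no activity
  n <- 500
  a <- triaxial_accel(rep(1, n), rep(-2, n), rep(0.5, n), fs = 100)
  expect_equal(activity_counts(a), rep(0, 5))

  # alternating +/-1 on one channel forces Act = 1
  x <- rep(c(1, -1), 150)
  a <- triaxial_accel(x, rep(0, 300), rep(3, 300), fs = 100)
  expect_equal(activity_counts(a), rep(1, 3))

  # random windows agree with the two-pass oracle; partial second dropped
  set.seed(41)
  fs <- 50
  x <- rnorm(fs * 7 + 13); y <- rnorm(fs * 7 + 13); z <- rnorm(fs * 7 + 13)
  a <- triaxial_accel(x, y, z, fs = fs)
  act <- activity_counts(a)
  expect_length(act, 7)
  expect_equal(act, oracle_activity(x, y, z, fs), tolerance = 1e-12)
})

test_that("instantaneous heart rate is piecewise-constant 60/IBI", {
  b <- beat_series(c(0, 0.5, 1.0))
  ihr <- compute_ihr(b, fs = 10)
  expect_equal(ihr$values[ihr$valid][1], 120)

  # worked two-beat evaluation
  b <- beat_series(c(0, 1.0, 1.8))
  ihr <- compute_ihr(b, fs = 100, duration = 2)
  tt <- series_times(ihr)
  expect_equal(ihr$values[which.min(abs(tt - 0.55))], 60)
  expect_equal(ihr$values[which.min(abs(tt - 1.05))], 75)
  expect_false(any(ihr$valid[tt >= 1.8]))

  # constant IBIs give constant IHR; changes only at beat times
  set.seed(5)
  tb <- cumsum(runif(30, 0.6, 1.2))
  ihr <- compute_ihr(beat_series(tb), fs = 200, t0 = 0,
                     duration = max(tb) + 1)
  tt <- series_times(ihr)
  chg <- which(diff(ihr$values[ihr$valid]) != 0)
  tchg <- tt[ihr$valid][chg + 1]
  for (tc in tchg)
    expect_lt(min(abs(tb - tc)), 1 / 200 + 1e-12)
})

test_that("quality masking invalidates exactly the governing intervals", {
  q <- c(1, 0, 1)
  b <- beat_series(c(0, 1, 2, 3), quality = c(q, 1))
  ihr <- compute_ihr(b, fs = 10, duration = 3)
  m <- mask_low_quality(ihr, b, q_min = 0.5)
  tt <- series_times(m)
  expect_false(any(m$valid[tt >= 1 & tt < 2]))
  expect_true(all(m$valid[tt < 1]))
  expect_true(all(m$valid[tt >= 2 & tt < 3]))

  expect_identical(mask_low_quality(ihr, b, q_min = 0), ihr)
  ball <- beat_series(c(0, 1, 2, 3))
  expect_identical(mask_low_quality(ihr, ball, q_min = 0.5)$valid, ihr$valid)
})

test_that("decimation preserves the passband and kills the stopband", {
  n <- 250 * 60
  tt <- (seq_len(n) - 1) / 250
  const <- triaxial_accel(rep(0.3, n), rep(-1, n), rep(0.7, n), fs = 250)
  d <- decimate_accel(const, 10)
  expect_equal(d$x, rep(0.3, length(d$x)), tolerance = 1e-12)
  expect_equal(d$fs, 10)

  s03 <- sin(2 * pi * 0.3 * tt)
  s30 <- sin(2 * pi * 30 * tt)
  a <- triaxial_accel(s03, s30, s03 + s30, fs = 250)
  d <- decimate_accel(a, 10)
  mid <- 100:(length(d$x) - 100)
  expect_gt(max(abs(d$x[mid])), 0.99)
  expect_lt(max(abs(d$x[mid])), 1.01)
  expect_lt(max(abs(d$y[mid])), 0.01)
  expect_error(decimate_accel(d, 10), "below")
})

test_that("orientation reads the sensor as a spirit level", {
  n <- 1200
  g <- triaxial_accel(rep(0, n), rep(0, n), rep(1, n), fs = 10)
  o <- to_orientation(g)
  expect_equal(o$v, rep(1, n), tolerance = 1e-9)
  expect_lt(max(abs(o$h1)), 1e-9)
  expect_lt(max(abs(o$h2)), 1e-9)

  # 5-degree tilt about one axis vs the gravity reference: alternate the
  # tilt sign every 5 s so the slowly varying gravity estimate stays on
  # the symmetry axis (z) while each plateau sits at the full tilt
  th <- 5 * pi / 180
  nt <- 6000
  sgn <- rep(rep(c(1, -1), each = 20), length.out = nt)
  a <- triaxial_accel(sin(th * sgn), rep(0, nt), cos(th * sgn), fs = 10)
  o <- to_orientation(a)
  # evaluate mid-plateau, away from filter transients and edges
  mid <- seq(10, nt, by = 20)
  mid <- mid[mid > 500 & mid < nt - 500]
  expect_lt(abs(mean(sqrt(o$h1[mid]^2 + o$h2[mid]^2)) - sin(th)), 1e-3)

  # unit-norm invariant on arbitrary input
  set.seed(8)
  a <- triaxial_accel(rnorm(500, 0, 0.3), rnorm(500, 0, 0.3),
                      rnorm(500, 1, 0.3), fs = 10)
  o <- to_orientation(a)
  nrm <- o$h1^2 + o$h2^2 + o$v^2
  expect_lt(max(abs(nrm[o$valid] - 1)), 1e-6)

  # near-zero samples are flagged invalid
  a <- triaxial_accel(c(rep(0, 5), rep(0, 5)), rep(0, 10),
                      c(rep(1, 5), rep(0.01, 5)), fs = 10)
  o <- to_orientation(a)
  expect_identical(o$valid, c(rep(TRUE, 5), rep(FALSE, 5)))
})

test_that("effort estimation recovers an oscillating tilt", {
  n <- 6000
  tt <- (seq_len(n) - 1) / 10
  tone <- sin(2 * pi * 0.25 * tt)
  orient <- structure(list(h1 = 0.05 * tone, h2 = rep(0, n),
                           v = sqrt(1 - (0.05 * tone)^2),
                           valid = rep(TRUE, n), fs = 10, t0 = 0),
                      class = "orientation_signal")
  res <- estimate_effort(orient)
  mid <- 600:(n - 600)
  expect_gt(abs(cor(res$values[mid], tone[mid])), 0.99)

  # constant orientation gives (numerically) zero effort
  orient0 <- structure(list(h1 = rep(0.02, n), h2 = rep(-0.01, n),
                            v = rep(sqrt(1 - 0.0005), n),
                            valid = rep(TRUE, n), fs = 10, t0 = 0),
                       class = "orientation_signal")
  res0 <- estimate_effort(orient0)
  expect_lt(max(abs(res0$values)), 1e-6)
})

test_that("activity mixing offsets by one and preserves gaps", {
  res <- gapped_series(rep(0.8, 50), 10, valid = c(rep(TRUE, 40), rep(FALSE, 10)))
  # zero activity: ResAct identical to Res
  out <- mix_effort(res, rep(0, 5), act_scale = 220)
  expect_identical(out$values, res$values)
  expect_identical(out$valid, res$valid)

  # Res 0.8 with scaled activity 0.5 gives 1.2
  out <- mix_effort(res, rep(0.5 / 220, 5), act_scale = 220)
  expect_equal(out$values, rep(0.8 * 1.5, 50))
  expect_identical(out$valid, res$valid)

  expect_error(mix_effort(res, rep(0, 4), act_scale = 220), "does not match")
})

test_that("beat detection recovers clean simulated beats", {
  rec <- get_clean_recording()
  ex <- extract_bundle(rec$accel)
  nn <- vapply(rec$true_beats$t, function(tb) min(abs(ex$beats$t - tb)),
               numeric(1))
  expect_gt(mean(nn <= 0.05), 0.95)

  # degenerate inputs
  expect_length(detect_heartbeats(numeric(1000), 100)$t, 0)
  expect_warning(b <- detect_heartbeats(rnorm(100), 100), "shorter")
  expect_length(b$t, 0)

  # pure noise scores low quality
  set.seed(12)
  bn <- detect_heartbeats(rnorm(60000, 0, 0.005), 100)
  expect_lt(mean(bn$quality), 0.4)
})

test_that("movement epochs dominate the mixed effort signal", {
  phys <- physiology_params()
  hyp <- stage_sequence(rep("L", 10))
  beats <- simulate_beats(hyp, phys, seed = 21)
  eff <- simulate_effort(hyp, phys, seed = 22)
  mov <- matrix(c(100, 103), ncol = 2)
  acc <- synthesize_acceleration(beats, eff, mov, phys, fs = 100, seed = 23)
  ex <- extract_bundle(acc)
  ra <- ex$bundle$resact$values
  sel <- rep(FALSE, length(ra))
  sel[(100 * 10):(103 * 10)] <- TRUE
  expect_gt(sqrt(mean(ra[sel]^2)), 3 * sqrt(mean(ra[!sel]^2)))
})
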