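test_that("hypnogram simulation respects the transition structure", {
  # absorbing Wake: identity matrix keeps the chain in its initial stage
  arch <- sleep_architecture(diag(4), c(1, 0, 0, 0), 50)
  hyp <- simulate_hypnogram(arch, seed = 1)
  expect_identical(hyp$labels, rep("W", 50))

  # uniform chain: empirical stage frequencies approach 1/4
  arch <- sleep_architecture(matrix(0.25, 4, 4), rep(0.25, 4), 40000)
  hyp <- simulate_hypnogram(arch, seed = 2)
  freq <- table(factor(hyp$labels, levels = stage_codes())) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))

  # determinism
  expect_identical(simulate_hypnogram(arch, seed = 9)$labels,
                   simulate_hypnogram(arch, seed = 9)$labels)
})

test_that("invalid architectures are rejected naming the offending row", {
  bad <- diag(4)
  bad[3, 3] <- 0.5
  expect_error(sleep_architecture(bad, c(1, 0, 0, 0), 10), "row 3")
  expect_error(sleep_architecture(-diag(4), c(1, 0, 0, 0), 10), "negative")
})

test_that("simulated beats track stage-conditional heart rate", {
  # zero variability at 60 bpm gives exactly 1-s IBIs
  phys0 <- physiology_params(
    hr_bpm = c(W = 60, L = 60, D = 60, R = 60),
    ibi_sdsd_s = c(W = 1e-12, L = 1e-12, D = 0, R = 1e-12))
  hyp <- stage_sequence(rep("L", 4))
  b <- simulate_beats(hyp, phys0, seed = 1)
  expect_equal(b$t, 0:119, tolerance = 1e-9)
  expect_true(all(abs(b$ibi[-length(b$ibi)] - 1) < 1e-9))

  # stage-conditional empirical means recover configured values within 2 bpm
  phys <- physiology_params(hr_bpm = c(W = 75, L = 62, D = 55, R = 66))
  arch <- sleep_architecture(matrix(0.25, 4, 4), rep(0.25, 4), 1000)
  hyp <- simulate_hypnogram(arch, seed = 3)
  b <- simulate_beats(hyp, phys, seed = 4)
  st <- accelsleep:::stage_at_time(hyp, b$t)
  hr <- 60 / b$ibi
  for (cl in c("W", "D")) {
    sel <- st == cl & !is.na(hr)
    expect_gt(sum(sel), 500)
    expect_lt(abs(mean(hr[sel]) - phys$hr_bpm[[cl]]), 2)
  }
  m <- tapply(hr, st, mean, na.rm = TRUE)
  expect_lt(m[["D"]], m[["W"]])

  # degenerate input and determinism
  expect_length(simulate_beats(stage_sequence(character(0)), phys, 1)$t, 0)
  expect_identical(simulate_beats(hyp, phys, 5)$t,
                   simulate_beats(hyp, phys, 5)$t)
})

test_that("clock skew retiming is affine and invertible", {
  hyp <- stage_sequence(rep("L", 4))
  b <- simulate_beats(hyp, physiology_params(), seed = 1)

  id <- inject_clock_skew(b, 0, 1)
  expect_equal(id$t, b$t)
  expect_equal(id$ibi, b$ibi)

  b1 <- beat_series(c(0, 500, 1000))
  sk <- inject_clock_skew(b1, 12.3, 1.0002)
  expect_equal(sk$t[3], 1012.5)

  back <- inject_clock_skew(inject_clock_skew(b, 7.7, 1.0005),
                            -7.7 / 1.0005, 1 / 1.0005)
  expect_true(max(abs(back$t - b$t)) < 1e-9)
})

test_that("synthesized acceleration carries the configured components", {
  # pure gravity: no cardiac pulses, no noise, no drift, constant effort
  phys <- physiology_params(cardiac_amp_g = 0, noise_sd_g = 0, drift_deg = 0)
  eff <- gapped_series(rep(0.4, 600), fs = 10)
  acc <- synthesize_acceleration(beat_series(numeric(0)), eff,
                                 matrix(numeric(0), ncol = 2), phys,
                                 fs = 100, seed = 1)
  for (ch in list(acc$x, acc$y, acc$z))
    expect_lt(diff(range(ch)), 1e-12)

  expect_error(synthesize_acceleration(beat_series(numeric(0)), eff,
                                       NULL, phys, fs = 40), ">= 50")

  # cardiac pulses at 10x noise: band-passed channel sum peaks near beats
  phys <- physiology_params(noise_sd_g = physiology_params()$cardiac_amp_g / 10,
                            move_rate_per_min = c(W = 0, L = 0, D = 0, R = 0))
  hyp <- stage_sequence(rep("L", 6))
  beats <- simulate_beats(hyp, phys, seed = 11)
  eff <- simulate_effort(hyp, phys, seed = 12)
  acc <- synthesize_acceleration(beats, eff, matrix(numeric(0), ncol = 2),
                                 phys, fs = 100, seed = 13)
  s <- collapse_channels(acc)
  flt <- signal::butter(4, c(5, 20) / 50, type = "pass")
  bp <- as.numeric(signal::filtfilt(flt, s - mean(s)))
  env <- abs(bp)
  hit <- vapply(beats$t, function(tb) {
    idx <- max(1, round((tb - 0.03) * 100)):min(length(env), round((tb + 0.03) * 100))
    # a local maximum of the band-passed magnitude falls within +/-30 ms
    any(diff(sign(diff(env[max(1, idx[1] - 1):min(length(env), idx[length(idx)] + 1)]))) == -2)
  }, logical(1))
  expect_gt(mean(hit), 0.95)

  # movement burst drives activity counts far above the quiet median
  phys <- physiology_params()
  mov <- matrix(c(100, 103), ncol = 2)
  acc <- synthesize_acceleration(beats, eff, mov, phys, fs = 100, seed = 14)
  act <- activity_counts(acc)
  expect_gt(min(act[101:103]), 10 * median(act))
})

test_that("simulated recordings are seed-deterministic", {
  arch <- default_sleep_architecture(n_epochs = 4)
  r1 <- simulate_recording(arch, seed = 7)
  r2 <- simulate_recording(arch, seed = 7)
  expect_identical(r1$hypnogram$labels, r2$hypnogram$labels)
  expect_identical(r1$true_beats$t, r2$true_beats$t)
  expect_identical(r1$accel$x, r2$accel$x)
  expect_true(all(r1$movement_intervals[, 2] <=
                    length(r1$hypnogram$labels) * 30))
  # acceleration covers the full recording
  expect_equal(length(r1$accel$x), 4 * 30 * 100)
})
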