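# Raw triaxial acceleration -> classifier inputs: beat series and gapped
# instantaneous heart rate, orientation-derived respiratory effort,
# per-second activity counts, and the actigraphy-modified effort signal.

# zero-phase Butterworth helpers; the mean is removed before filtering and
# (for low-pass) restored afterwards, so constant inputs pass through
# exactly and edge transients stay small
lp_filter <- function(x, order, cutoff_hz, fs) {
  m <- mean(x)
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(flt, x - m)) + m
}

bp_filter <- function(x, order, band_hz, fs) {
  flt <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, x - mean(x)))
}

#' Collapse the three acceleration channels into one
#'
#' Sample-wise arithmetic addition `x + y + z`; the cardiac "small peaks"
#' survive the sum regardless of sensor orientation.
#'
#' @param accel A [triaxial_accel()].
#' @return Numeric vector, same length and rate as the input channels.
#' @export
collapse_channels <- function(accel) {
  stopifnot(inherits(accel, "triaxial_accel"))
  accel$x + accel$y + accel$z
}

# local periodicity strength: autocorrelation peak ratio of the (centered)
# envelope in +/- half_s windows on a coarse grid, in [0, 1]. The raw
# peak ratio saturates well below 1 on clean signals because IBI
# variability smears the autocorrelation peak, so the ratio is rescaled
# by `ratio_scale` (calibrated once on clean and pure-noise simulations
# so that clean cardiac signal maps near 1 and noise stays below 0.4)
# and clipped to [0, 1].
periodicity_grid <- function(env, fs, ibi_bounds, half_s = 5, hop_s = 2,
                             ratio_scale = 0.5) {
  n <- length(env)
  half <- round(half_s * fs)
  centers <- seq(1L, n, by = max(1L, round(hop_s * fs)))
  lag_lo <- max(1L, floor(ibi_bounds[1] * fs))
  lag_hi <- min(2L * half - 1L, ceiling(ibi_bounds[2] * fs))
  q <- numeric(length(centers))
  for (i in seq_along(centers)) {
    i1 <- max(1L, centers[i] - half)
    i2 <- min(n, centers[i] + half)
    wdw <- env[i1:i2] - mean(env[i1:i2])
    m <- length(wdw)
    if (m < lag_lo + 2L || sum(wdw^2) == 0) { q[i] <- 0; next }
    nf <- stats::nextn(2L * m, 2)
    sp <- stats::fft(c(wdw, numeric(nf - m)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:m] / nf
    hi <- min(lag_hi, m - 1L)
    if (hi < lag_lo) { q[i] <- 0; next }
    ratio <- max(ac[(lag_lo + 1L):(hi + 1L)]) / ac[1]
    q[i] <- max(0, min(1, ratio / ratio_scale))
  }
  list(t = (centers - 1) / fs, q = q)
}

#' Localize heartbeats in the collapsed acceleration signal
#'
#' The signal is band-passed to 5--20 Hz where the seismocardiographic
#' pulses live, its smoothed envelope is peak-picked, and the beat
#' sequence is the exact maximizer of
#' `sum(normalized envelope amplitude) - smoothness_weight *
#' sum((IBI[i+1] - IBI[i])^2)` over admissible peak subsequences
#' (successive gaps within `ibi_bounds`), solved by dynamic programming
#' over candidate peaks. Each beat carries a quality score in `[0, 1]`:
#' the autocorrelation peak ratio of the envelope in a +/-5 s window,
#' which collapses during movement artifacts and noise.
#'
#' @param s Collapsed acceleration (numeric vector).
#' @param fs Sampling rate in Hz (`>= 50`).
#' @param ibi_bounds Admissible inter-beat interval range in seconds
#'   (default `c(1/3, 2)`, i.e. 30--180 bpm).
#' @param smoothness_weight Weight of the squared successive-IBI-difference
#'   penalty (default 10; envelope amplitudes are normalized to unit
#'   scale, IBIs are in seconds).
#' @param peak_cost Amplitude offset subtracted from every accepted peak
#'   (default 0.4 of the normalized scale). Without it the maximizer
#'   would profit from inserting every admissible low-amplitude peak;
#'   the cost makes accepting a peak worthwhile only when its envelope
#'   amplitude clears the noise floor.
#' @return A [beat_series()] with per-beat quality. Recordings shorter
#'   than twice the upper IBI bound give an empty series with a warning.
#' @export
detect_heartbeats <- function(s, fs, ibi_bounds = c(1 / 3, 2),
                              smoothness_weight = 10, peak_cost = 0.4) {
  if (fs < 50) stop("fs must be >= 50 Hz")
  if (!(ibi_bounds[1] > 0 && ibi_bounds[1] < ibi_bounds[2]))
    stop("ibi_bounds must satisfy 0 < lo < hi")
  empty <- beat_series(numeric(0))
  if (length(s) < 2 * ibi_bounds[2] * fs) {
    warning("recording shorter than twice the upper IBI bound; no beats")
    return(empty)
  }
  if (all(s == 0)) return(empty)

  bp <- bp_filter(s, 4, c(5, 20), fs)
  env <- lp_filter(abs(bp), 2, 10, fs)
  env[env < 0] <- 0

  pk <- which(diff(sign(diff(env))) == -2) + 1L
  if (length(pk) < 2) return(empty)
  # normalize so a typical cardiac peak is ~1; movement bursts dwarf the
  # cardiac scale, so peaks beyond 20x the median are excluded first
  h <- env[pk]
  med <- stats::median(h)
  scale <- stats::quantile(h[h <= 20 * med], 0.9, names = FALSE)
  if (!is.finite(scale) || scale <= 0) return(empty)
  a <- pmin(env[pk] / scale, 2) - peak_cost
  tpk <- (pk - 1) / fs

  path <- dp_beat_path(tpk, a, ibi_bounds[1], ibi_bounds[2], smoothness_weight)
  if (length(path) < 2) return(empty)
  tb <- tpk[path]

  env_q <- lp_filter(abs(bp), 2, 3, fs)  # wider pulses survive IBI jitter
  grid <- periodicity_grid(env_q, fs, ibi_bounds)
  qb <- stats::approx(grid$t, grid$q, xout = tb, rule = 2)$y
  beat_series(tb, quality = pmin(pmax(qb, 0), 1))
}

#' Instantaneous heart rate from a beat series
#'
#' `IHR[i] = 60 / IBI[i]` in bpm, held constant over each beat's hold
#' interval `[t[i], t[i+1])` and sampled at `fs` (sample-and-hold
#' upsampling). Samples before the first beat or at/after the last beat
#' are invalid.
#'
#' @param beats A [beat_series()].
#' @param fs Output rate in Hz (default 10).
#' @param t0 Grid start time in seconds (default 0).
#' @param duration Grid duration in seconds; defaults to covering the
#'   last beat.
#' @return A [gapped_series()] in bpm.
#' @export
compute_ihr <- function(beats, fs = 10, t0 = 0, duration = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(duration)) {
    if (length(beats$t) == 0) return(gapped_series(numeric(0), fs, t0 = t0))
    duration <- max(beats$t) - t0 + 1 / fs
  }
  n <- max(0L, round(duration * fs))
  tt <- t0 + (seq_len(n) - 1L) / fs
  if (length(beats$t) == 0)
    return(gapped_series(rep(NA_real_, n), fs, valid = rep(FALSE, n), t0 = t0))
  idx <- findInterval(tt, beats$t)
  valid <- idx >= 1L & !is.na(beats$ibi[pmax(idx, 1L)]) &
    tt < beats$t[pmax(idx, 1L)] + beats$ibi[pmax(idx, 1L)]
  vals <- rep(NA_real_, n)
  vals[valid] <- 60 / beats$ibi[idx[valid]]
  gapped_series(vals, fs, valid = valid, t0 = t0)
}

#' Mask IHR samples governed by low-quality beats
#'
#' Samples whose hold interval belongs to a beat with quality below
#' `q_min` become invalid, producing the characteristic gaps at movement
#' artifacts.
#'
#' @param ihr A [gapped_series()] produced by [compute_ihr()].
#' @param beats The [beat_series()] the IHR was derived from.
#' @param q_min Quality threshold in `[0, 1]` (default 0.5); 0 masks
#'   nothing.
#' @return The masked [gapped_series()].
#' @export
mask_low_quality <- function(ihr, beats, q_min = 0.5) {
  stopifnot(inherits(ihr, "gapped_series"), inherits(beats, "beat_series"))
  if (q_min < 0 || q_min > 1) stop("q_min must lie in [0, 1]")
  if (q_min == 0 || length(beats$t) == 0) return(ihr)
  tt <- series_times(ihr)
  idx <- findInterval(tt, beats$t)
  bad <- idx >= 1L & beats$quality[pmax(idx, 1L)] < q_min
  ihr$valid <- ihr$valid & !bad
  ihr$values[!ihr$valid] <- NA_real_
  ihr
}

#' Anti-aliased decimation of a triaxial recording
#'
#' Zero-phase low-pass (cutoff `0.4 * target_fs`, below the 0.45
#' anti-aliasing bound) followed by resampling; channel means are
#' restored so constant inputs are preserved exactly. Non-integer rate
#' ratios fall back to linear interpolation of the filtered signal.
#'
#' @param accel A [triaxial_accel()].
#' @param target_fs Target rate in Hz (default 10); must be below `fs`.
#' @return The decimated [triaxial_accel()].
#' @export
decimate_accel <- function(accel, target_fs = 10) {
  stopifnot(inherits(accel, "triaxial_accel"))
  if (target_fs >= accel$fs) stop("target_fs must be below the input rate")
  dec1 <- function(v) {
    f <- lp_filter(v, 4, 0.4 * target_fs, accel$fs)
    ratio <- accel$fs / target_fs
    if (abs(ratio - round(ratio)) < 1e-9) {
      f[seq(1L, length(f), by = round(ratio))]
    } else {
      tt <- (seq_along(f) - 1) / accel$fs
      to <- seq(0, max(tt), by = 1 / target_fs)
      stats::approx(tt, f, xout = to)$y
    }
  }
  triaxial_accel(dec1(accel$x), dec1(accel$y), dec1(accel$z),
                 target_fs, t0 = accel$t0)
}

#' Orientation signal from 10 Hz acceleration
#'
#' Reads the sensor as a 2D spirit level: each acceleration sample is
#' unit-normalized; the slowly varying gravity direction is its 0.05 Hz
#' low-pass; `v` is the projection onto gravity and `(h1, h2)` the
#' components in the orthogonal plane, with the first basis vector the
#' normalized projection of the device x-axis onto that plane (so the
#' basis is deterministic). `h1^2 + h2^2 + v^2 = 1` at every valid
#' sample. Samples with vector norm below 0.1 g are invalid.
#'
#' @param accel10 A 10 Hz [triaxial_accel()].
#' @return An `orientation_signal`: list with `h1`, `h2`, `v`, `valid`,
#'   `fs`, `t0`.
#' @export
to_orientation <- function(accel10) {
  stopifnot(inherits(accel10, "triaxial_accel"))
  if (abs(accel10$fs - 10) > 1e-9) stop("orientation expects a 10 Hz input")
  m <- cbind(accel10$x, accel10$y, accel10$z)
  nrm <- sqrt(rowSums(m^2))
  valid <- nrm >= 0.1
  nrm_safe <- ifelse(valid, nrm, 1)
  u <- m / nrm_safe
  # carry last valid direction through invalid stretches for filtering
  if (any(!valid) && any(valid)) {
    for (j in 1:3) {
      v <- u[, j]
      v[!valid] <- NA
      u[, j] <- fill_hold(v)
    }
  }
  n <- nrow(u)
  g <- if (n >= 200) {
    apply(u, 2, function(col) lp_filter(col, 2, 0.05, accel10$fs))
  } else {
    matrix(colMeans(u), n, 3, byrow = TRUE)
  }
  g <- g / sqrt(rowSums(g^2))
  # horizontal basis from the device x-axis (y-axis where degenerate)
  ex <- c(1, 0, 0)
  e1 <- cbind(ex[1] - g[, 1] * g[, 1], ex[2] - g[, 1] * g[, 2],
              ex[3] - g[, 1] * g[, 3])
  n1 <- sqrt(rowSums(e1^2))
  deg <- n1 < 1e-6
  if (any(deg)) {
    e1[deg, ] <- cbind(-g[deg, 2] * g[deg, 1], 1 - g[deg, 2] * g[deg, 2],
                       -g[deg, 2] * g[deg, 3])
    n1 <- sqrt(rowSums(e1^2))
  }
  e1 <- e1 / n1
  e2 <- cbind(g[, 2] * e1[, 3] - g[, 3] * e1[, 2],
              g[, 3] * e1[, 1] - g[, 1] * e1[, 3],
              g[, 1] * e1[, 2] - g[, 2] * e1[, 1])
  structure(list(h1 = rowSums(u * e1), h2 = rowSums(u * e2),
                 v = rowSums(u * g), valid = valid, fs = accel10$fs,
                 t0 = accel10$t0),
            class = "orientation_signal")
}

# sample-and-hold fill of NAs (leading NAs backfilled)
fill_hold <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  idx <- cummax(ifelse(ok, seq_along(v), 0L))
  first <- which(ok)[1]
  idx[idx == 0L] <- first
  v[idx]
}

#' Respiratory effort from the orientation signal
#'
#' Transparent estimator standing behind the respiratory-effort contract
#' (10 Hz effort in, arbitrary units out): projects `(h1, h2)` onto
#' their locally dominant direction (principal axis of the covariance in
#' a sliding 60-s window), band-passes to the 0.1--0.7 Hz respiratory
#' band, and normalizes to unit interquartile range per 5-min window.
#' Invalid orientation samples propagate to the output mask.
#'
#' @param orient An `orientation_signal` from [to_orientation()].
#' @param window_s Principal-direction window length (s, default 60).
#' @param norm_window_s Amplitude-normalization window (s, default 300).
#' @return A [gapped_series()] at 10 Hz.
#' @export
estimate_effort <- function(orient, window_s = 60, norm_window_s = 300) {
  stopifnot(inherits(orient, "orientation_signal"))
  fs <- orient$fs
  n <- length(orient$h1)
  if (n == 0) return(gapped_series(numeric(0), fs))
  h1 <- orient$h1
  h2 <- orient$h2
  win <- min(n, round(window_s * fs))
  hop <- max(1L, round(5 * fs))
  centers <- seq(1L, n, by = hop)
  c2 <- s2 <- numeric(length(centers))
  for (i in seq_along(centers)) {
    i1 <- max(1L, centers[i] - win %/% 2)
    i2 <- min(n, centers[i] + win %/% 2)
    a <- h1[i1:i2] - mean(h1[i1:i2])
    b <- h2[i1:i2] - mean(h2[i1:i2])
    cxx <- mean(a * a); cyy <- mean(b * b); cxy <- mean(a * b)
    ang2 <- atan2(2 * cxy, cxx - cyy)  # doubled principal angle
    c2[i] <- cos(ang2); s2[i] <- sin(ang2)
  }
  cc <- stats::approx(centers, c2, xout = seq_len(n), rule = 2)$y
  ss <- stats::approx(centers, s2, xout = seq_len(n), rule = 2)$y
  theta <- 0.5 * atan2(ss, cc)
  proj <- h1 * cos(theta) + h2 * sin(theta)
  res <- if (n > 50) bp_filter(proj, 2, c(0.1, 0.7), fs) else proj - mean(proj)

  # block-wise IQR normalization, scale interpolated between block centers
  blk <- max(1L, round(norm_window_s * fs))
  starts <- seq(1L, n, by = blk)
  sc <- vapply(starts, function(s0) {
    seg <- res[s0:min(n, s0 + blk - 1L)]
    stats::IQR(seg)
  }, numeric(1))
  sc <- pmax(sc, 1e-12)
  mid <- pmin(starts + blk / 2, n)
  scale <- if (length(starts) > 1)
    stats::approx(mid, sc, xout = seq_len(n), rule = 2)$y
  else rep(sc, n)
  gapped_series(res / scale, fs, valid = orient$valid, t0 = orient$t0)
}

#' Per-second activity counts
#'
#' For every full second of the recording, the mean absolute deviation
#' from the within-second mean is computed per channel and summed over
#' the three channels:
#' `Act = mean(|x - xbar|) + mean(|y - ybar|) + mean(|z - zbar|)`.
#' A trailing partial second is dropped.
#'
#' @param accel A [triaxial_accel()] with integer `fs >= 1`.
#' @return Numeric vector of non-negative counts at 1 Hz.
#' @export
activity_counts <- function(accel) {
  stopifnot(inherits(accel, "triaxial_accel"))
  N <- round(accel$fs)
  if (N < 1 || abs(accel$fs - N) > 1e-9)
    stop("activity counts need an integer sampling rate >= 1 Hz")
  nsec <- length(accel$x) %/% N
  if (nsec == 0) return(numeric(0))
  mad1 <- function(v) {
    m <- matrix(v[seq_len(nsec * N)], nrow = N)
    colMeans(abs(m - rep(colMeans(m), each = N)))
  }
  mad1(accel$x) + mad1(accel$y) + mad1(accel$z)
}

#' Mix activity counts into the respiratory effort signal
#'
#' Restores the movement artifacts a thoracic-belt sensor would show:
#' activity is sample-and-hold upsampled to 10 Hz, scaled, offset by 1.0
#' so quiet periods leave the effort untouched, and multiplied into the
#' effort: `ResAct = (1 + act_scale * Act) * Res`.
#'
#' @param res A 10 Hz [gapped_series()] respiratory effort.
#' @param act1hz 1 Hz activity counts; must cover the same full seconds
#'   as `res` (`length(res) == 10 * length(act1hz)`).
#' @param act_scale Positive scale factor; the packaged default makes the
#'   95th percentile of scaled activity about 5 on a calibration
#'   simulation, so movement clearly dominates the product.
#' @return A [gapped_series()] `ResAct`; invalid `res` samples stay
#'   invalid.
#' @export
mix_effort <- function(res, act1hz, act_scale = default_config()$act_scale) {
  stopifnot(inherits(res, "gapped_series"))
  if (act_scale <= 0) stop("act_scale must be positive")
  act10 <- rep(as.numeric(act1hz), each = round(res$fs))
  if (length(act10) != length(res$values))
    stop(sprintf("activity (%d upsampled samples) does not match effort (%d)",
                 length(act10), length(res$values)))
  out <- (1 + act_scale * act10) * res$values
  gapped_series(out, res$fs, valid = res$valid, t0 = res$t0)
}

#' Full feature extraction from raw acceleration
#'
#' Runs the extraction chain: channel collapse, beat localization and
#' quality masking, sample-and-hold IHR at 10 Hz, decimation to 10 Hz,
#' orientation, respiratory effort, activity counts, and the ResAct mix.
#' All 10 Hz signals are trimmed to the recording's full seconds.
#'
#' @param accel A [triaxial_accel()].
#' @param config A [default_config()]-style list of tunables.
#' @return A list with the [effort_bundle()] (`bundle`) and the detected
#'   [beat_series()] (`beats`).
#' @export
extract_bundle <- function(accel, config = default_config()) {
  stopifnot(inherits(accel, "triaxial_accel"))
  nsec <- floor(length(accel$x) / accel$fs)
  n10 <- nsec * 10L

  s <- collapse_channels(accel)
  beats <- detect_heartbeats(s, accel$fs, config$ibi_bounds,
                             config$smoothness_weight)
  ihr <- compute_ihr(beats, fs = 10, t0 = accel$t0, duration = nsec)
  ihr <- mask_low_quality(ihr, beats, config$q_min)

  acc10 <- decimate_accel(accel, 10)
  orient <- to_orientation(acc10)
  res <- estimate_effort(orient)
  res <- gapped_series(res$values[seq_len(n10)], 10,
                       valid = res$valid[seq_len(n10)], t0 = res$t0)

  act1 <- activity_counts(accel)[seq_len(nsec)]
  resact <- mix_effort(res, act1, config$act_scale)
  act10 <- rep(act1, each = 10L)
  list(bundle = effort_bundle(ihr, res, act10, act1, resact), beats = beats)
}
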