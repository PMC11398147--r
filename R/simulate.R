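# Synthetic overnight recordings: hypnogram -> stage-conditional beats,
# respiratory effort and movement bursts -> triaxial acceleration. Every
# downstream module is testable against the ground truth produced here.

#' Sleep architecture for the hypnogram simulator
#'
#' A first-order Markov chain over the four stages at 30-s epoch
#' resolution.
#'
#' @param transition 4x4 row-stochastic matrix, rows/columns in the
#'   canonical order `W, L, D, R` (see [stage_codes()]).
#' @param initial Length-4 initial stage distribution (sums to 1).
#' @param n_epochs Number of 30-s epochs to simulate.
#' @return A `sleep_architecture` object.
#' @export
sleep_architecture <- function(transition, initial, n_epochs) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4, 4)))
    stop("transition matrix must be 4x4 over (W, L, D, R)")
  check_stochastic(transition, "transition matrix")
  initial <- as.numeric(initial)
  if (length(initial) != 4 || any(initial < 0) || abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must be a length-4 probability vector")
  if (!is.numeric(n_epochs) || n_epochs < 0 || n_epochs != round(n_epochs))
    stop("n_epochs must be a non-negative integer")
  dimnames(transition) <- list(stage_codes(), stage_codes())
  names(initial) <- stage_codes()
  structure(list(transition = transition, initial = initial,
                 n_epochs = as.integer(n_epochs)),
            class = "sleep_architecture")
}

#' Default sleep architecture
#'
#' Reads the packaged transition-matrix configuration: a chain biased
#' toward long N1+N2 runs with occasional N3 and REM periods and brief
#' awakenings, starting from Wake. The matrix lives in a config file so
#' study conditions can be changed without touching code.
#'
#' @param n_epochs Number of 30-s epochs (default 960, an 8-h night).
#' @param config Path to an architecture YAML file; defaults to the
#'   packaged one.
#' @return A `sleep_architecture`.
#' @export
default_sleep_architecture <- function(n_epochs = 960, config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "default_architecture.yaml",
                          package = "accelsleep", mustWork = TRUE)
  cfg <- yaml::read_yaml(config)
  tm <- do.call(rbind, lapply(cfg$transition, as.numeric))
  sleep_architecture(tm, as.numeric(cfg$initial), n_epochs)
}

#' Stage-conditional physiology parameters
#'
#' Defaults encode the autonomic patterns the staging method exploits:
#' heart rate drops and stabilizes in deep non-REM sleep, REM shows high
#' heart-rate variability and irregular breathing, breathing is most
#' regular in N3, and gross body movement concentrates in Wake. Values
#' are literature-plausible round numbers, not fitted to any cohort.
#'
#' @param hr_bpm Named per-stage mean heart rate (bpm).
#' @param ibi_sdsd_s Named per-stage IBI variability: std of successive
#'   IBI differences (s).
#' @param resp_rate_hz Named per-stage mean respiratory rate (Hz).
#' @param resp_jitter Named per-stage fractional cycle-to-cycle rate
#'   jitter.
#' @param move_rate_per_min Named per-stage movement-burst rate
#'   (events/min).
#' @param move_amp_g Movement burst amplitude (g).
#' @param cardiac_amp_g Cardiac pulse peak amplitude (g).
#' @param noise_sd_g Sensor white-noise std (g).
#' @param pulse_freq_hz,pulse_sigma_s Cardiac pulse carrier frequency and
#'   Gaussian envelope width; defaults put the pulse energy inside the
#'   5--20 Hz band the beat detector searches.
#' @param resp_tilt_deg Peak sensor tilt driven by respiration (degrees,
#'   small-angle).
#' @param drift_deg,drift_period_s Amplitude and period of the slow
#'   gravity-orientation drift (posture-like).
#' @return A validated `physiology_params` object.
#' @export
physiology_params <- function(
    hr_bpm = c(W = 70, L = 62, D = 57, R = 66),
    ibi_sdsd_s = c(W = 0.050, L = 0.035, D = 0.020, R = 0.060),
    resp_rate_hz = c(W = 0.27, L = 0.23, D = 0.21, R = 0.28),
    resp_jitter = c(W = 0.08, L = 0.03, D = 0.02, R = 0.12),
    move_rate_per_min = c(W = 2, L = 0.2, D = 0.05, R = 0.15),
    move_amp_g = 0.5,
    cardiac_amp_g = 0.01,
    noise_sd_g = 0.001,
    pulse_freq_hz = 15,
    pulse_sigma_s = 0.015,
    resp_tilt_deg = 3,
    drift_deg = 2,
    drift_period_s = 1200) {
  p <- list(hr_bpm = hr_bpm[stage_codes()], ibi_sdsd_s = ibi_sdsd_s[stage_codes()],
            resp_rate_hz = resp_rate_hz[stage_codes()],
            resp_jitter = resp_jitter[stage_codes()],
            move_rate_per_min = move_rate_per_min[stage_codes()],
            move_amp_g = move_amp_g, cardiac_amp_g = cardiac_amp_g,
            noise_sd_g = noise_sd_g, pulse_freq_hz = pulse_freq_hz,
            pulse_sigma_s = pulse_sigma_s, resp_tilt_deg = resp_tilt_deg,
            drift_deg = drift_deg, drift_period_s = drift_period_s)
  if (anyNA(unlist(p[c("hr_bpm", "ibi_sdsd_s", "resp_rate_hz", "resp_jitter",
                       "move_rate_per_min")])))
    stop("per-stage parameters must be named for all of W, L, D, R")
  if (any(p$hr_bpm < 30 | p$hr_bpm > 180))
    stop("heart rates must lie in [30, 180] bpm")
  if (any(p$resp_rate_hz < 0.1 | p$resp_rate_hz > 0.7))
    stop("respiratory rates must lie in [0.1, 0.7] Hz")
  nonneg <- c(p$ibi_sdsd_s, p$resp_jitter, p$move_rate_per_min, p$move_amp_g,
              p$cardiac_amp_g, p$noise_sd_g)
  if (any(nonneg < 0)) stop("variabilities and amplitudes must be >= 0")
  if (!(p$ibi_sdsd_s["W"] > p$ibi_sdsd_s["D"] &&
        p$ibi_sdsd_s["R"] > p$ibi_sdsd_s["D"]))
    stop("Wake and REM IBI variability must exceed N3 variability")
  if (!(max(p$resp_jitter[c("L", "D")]) < min(p$resp_jitter[c("W", "R")])))
    stop("respiratory jitter must be lower in NREM than in Wake/REM")
  structure(p, class = "physiology_params")
}

# deterministic child-stream seeds from one root seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.numeric(seed) %% 65011 + 1) * 32749 + 101 * k
}

#' Simulate a hypnogram from a Markov sleep architecture
#'
#' @param arch A [sleep_architecture()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A [stage_sequence()] of `arch$n_epochs` labels.
#' @export
simulate_hypnogram <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "sleep_architecture"))
  n <- arch$n_epochs
  if (n == 0) return(stage_sequence(character(0)))
  set.seed(seed)
  codes <- stage_codes()
  lab <- integer(n)
  lab[1] <- sample.int(4, 1, prob = arch$initial)
  if (n > 1) {
    u <- stats::runif(n - 1)
    cum <- t(apply(arch$transition, 1, cumsum))
    for (i in 2:n)
      lab[i] <- findInterval(u[i - 1], cum[lab[i - 1], ], left.open = TRUE) + 1L
  }
  stage_sequence(codes[lab])
}

# stage code of the epoch containing each time (times past the end keep the
# last epoch's stage)
stage_at_time <- function(hyp, t) {
  idx <- pmin(pmax(floor(t / hyp$epoch_s) + 1L, 1L), length(hyp$labels))
  hyp$labels[idx]
}

#' Simulate heartbeats conditional on a hypnogram
#'
#' Beat times are generated sequentially; each inter-beat interval is
#' drawn around the stage mean `60 / HR` with a Gaussian deviation whose
#' scale reproduces the configured std of successive IBI differences
#' (`sd = sdsd / sqrt(2)` for independent deviations), clamped to the
#' physiological 30--180 bpm range.
#'
#' @param hyp A [stage_sequence()] hypnogram.
#' @param phys A [physiology_params()].
#' @param seed Integer seed.
#' @return A [beat_series()] covering the recording.
#' @export
simulate_beats <- function(hyp, phys, seed = 1) {
  stopifnot(inherits(hyp, "stage_sequence"), inherits(phys, "physiology_params"))
  dur <- length(hyp$labels) * hyp$epoch_s
  if (dur == 0) return(beat_series(numeric(0)))
  set.seed(seed)
  mu <- 60 / phys$hr_bpm
  sig <- phys$ibi_sdsd_s / sqrt(2)
  n_max <- ceiling(dur / min(mu)) + ceiling(dur / 2) + 10L
  t <- numeric(n_max)
  cur <- 0
  k <- 0L
  z <- stats::rnorm(n_max)
  while (cur < dur) {
    k <- k + 1L
    t[k] <- cur
    st <- stage_at_time(hyp, cur)
    ibi <- mu[[st]] + sig[[st]] * z[k]
    ibi <- min(max(ibi, 60 / 180), 60 / 30)
    cur <- cur + ibi
  }
  beat_series(t[seq_len(k)])
}

#' Simulate a 10 Hz respiratory effort signal
#'
#' Breath-by-breath generation: each cycle's rate is the stage mean
#' perturbed by the stage's fractional jitter, clamped to 0.1--0.7 Hz;
#' within a cycle the phase advances linearly and the waveform is a
#' sinusoid with mild (5%) cycle-to-cycle amplitude variation.
#'
#' @inheritParams simulate_beats
#' @return A [gapped_series()] at 10 Hz (all valid), arbitrary units.
#' @export
simulate_effort <- function(hyp, phys, seed = 1) {
  stopifnot(inherits(hyp, "stage_sequence"), inherits(phys, "physiology_params"))
  dur <- length(hyp$labels) * hyp$epoch_s
  if (dur == 0) return(gapped_series(numeric(0), fs = 10))
  set.seed(seed)
  n_br_max <- ceiling(dur * 0.7) + 10L
  zr <- stats::rnorm(n_br_max)
  za <- stats::rnorm(n_br_max)
  starts <- numeric(n_br_max)
  durs <- numeric(n_br_max)
  amps <- numeric(n_br_max)
  cur <- 0
  k <- 0L
  while (cur < dur) {
    k <- k + 1L
    st <- stage_at_time(hyp, cur)
    f <- phys$resp_rate_hz[[st]] * (1 + phys$resp_jitter[[st]] * zr[k])
    f <- min(max(f, 0.1), 0.7)
    starts[k] <- cur
    durs[k] <- 1 / f
    amps[k] <- 1 + 0.05 * za[k]
    cur <- cur + 1 / f
  }
  starts <- starts[seq_len(k)]; durs <- durs[seq_len(k)]; amps <- amps[seq_len(k)]
  tt <- seq(0, dur - 0.1, by = 0.1)
  br <- findInterval(tt, starts)
  phase <- 2 * pi * (tt - starts[br]) / durs[br]
  gapped_series(amps[br] * sin(phase), fs = 10)
}

#' Simulate gross-body-movement intervals
#'
#' Poisson bursts per epoch at the stage's configured rate; burst
#' durations uniform on 0.5--3 s; overlapping bursts are merged.
#'
#' @inheritParams simulate_beats
#' @return A two-column matrix `(start_s, end_s)`, possibly empty.
#' @export
simulate_movements <- function(hyp, phys, seed = 1) {
  stopifnot(inherits(hyp, "stage_sequence"), inherits(phys, "physiology_params"))
  n <- length(hyp$labels)
  if (n == 0) return(matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("start_s", "end_s"))))
  set.seed(seed)
  dur <- n * hyp$epoch_s
  rate <- phys$move_rate_per_min[hyp$labels] * hyp$epoch_s / 60
  counts <- stats::rpois(n, rate)
  iv <- NULL
  for (i in which(counts > 0)) {
    s <- (i - 1) * hyp$epoch_s + stats::runif(counts[i], 0, hyp$epoch_s)
    d <- stats::runif(counts[i], 0.5, 3)
    iv <- rbind(iv, cbind(s, pmin(s + d, dur)))
  }
  if (is.null(iv))
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (j in 2:nrow(iv)) {
    last <- nrow(merged)
    if (iv[j, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], iv[j, 2])
    } else merged <- rbind(merged, iv[j, , drop = FALSE])
  }
  dimnames(merged) <- list(NULL, c("start_s", "end_s"))
  merged
}

#' Synthesize triaxial acceleration from simulated physiology
#'
#' The channel model follows what a chest sensor sees: a slowly drifting
#' gravity vector, respiration as a small-angle tilt of that vector, one
#' short Gaussian-windowed sinusoidal pulse per heartbeat on the chest
#' normal (the seismocardiographic "small peak"), broadband bursts inside
#' movement intervals, and white sensor noise.
#'
#' @param beats A [beat_series()] of true beat times.
#' @param effort 10 Hz [gapped_series()] respiratory effort (unit scale).
#' @param movements Two-column matrix of movement intervals (s).
#' @param phys A [physiology_params()].
#' @param fs Output sampling rate in Hz, `>= 50` so cardiac pulses are
#'   resolved (default 100; 250 matches the reference hardware).
#' @param seed Integer seed (noise and burst streams).
#' @return A [triaxial_accel()].
#' @export
synthesize_acceleration <- function(beats, effort, movements, phys,
                                    fs = 100, seed = 1) {
  stopifnot(inherits(beats, "beat_series"), inherits(effort, "gapped_series"),
            inherits(phys, "physiology_params"))
  if (fs < 50) stop("fs must be >= 50 Hz to resolve cardiac pulses")
  dur <- length(effort$values) / effort$fs
  n <- round(dur * fs)
  if (n == 0) return(triaxial_accel(numeric(0), numeric(0), numeric(0), fs))
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs

  # respiration tilt + slow drift, small-angle rotation of gravity (0,0,1)
  eff_fs <- stats::approx(series_times(effort), effort$values, xout = t,
                          rule = 2)$y
  theta <- phys$resp_tilt_deg * pi / 180 * eff_fs
  drift_phase <- stats::runif(2, 0, 2 * pi)
  phi <- phys$drift_deg * pi / 180 *
    sin(2 * pi * t / phys$drift_period_s + drift_phase[1])
  psi <- 0.3 * phys$drift_deg * pi / 180 *
    sin(2 * pi * t / (0.73 * phys$drift_period_s) + drift_phase[2])
  ax <- sin(psi)
  ay <- sin(theta + phi) * cos(psi)
  az <- sqrt(pmax(1 - ax^2 - ay^2, 0))

  # one cardiac pulse per beat on the chest-normal channel
  if (length(beats$t) > 0 && phys$cardiac_amp_g > 0) {
    half <- ceiling(4 * phys$pulse_sigma_s * fs)
    koff <- (-half):half
    for (tb in beats$t) {
      i0 <- round(tb * fs) + 1L
      idx <- i0 + koff
      keep <- idx >= 1L & idx <= n
      tau <- (idx[keep] - 1) / fs - tb
      az[idx[keep]] <- az[idx[keep]] + phys$cardiac_amp_g *
        sin(2 * pi * phys$pulse_freq_hz * tau) * exp(-tau^2 / (2 * phys$pulse_sigma_s^2))
    }
  }

  # broadband bursts inside movement intervals, raised-cosine ramped
  if (!is.null(movements) && nrow(movements) > 0 && phys$move_amp_g > 0) {
    ramp_s <- 0.25
    for (j in seq_len(nrow(movements))) {
      i1 <- max(1L, floor(movements[j, 1] * fs) + 1L)
      i2 <- min(n, ceiling(movements[j, 2] * fs))
      if (i2 < i1) next
      m <- i2 - i1 + 1L
      env <- rep(1, m)
      nr <- min(floor(ramp_s * fs), floor(m / 2))
      if (nr > 0) {
        w <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        env[seq_len(nr)] <- w
        env[m + 1 - seq_len(nr)] <- w
      }
      ax[i1:i2] <- ax[i1:i2] + phys$move_amp_g * env * stats::rnorm(m)
      ay[i1:i2] <- ay[i1:i2] + phys$move_amp_g * env * stats::rnorm(m)
      az[i1:i2] <- az[i1:i2] + phys$move_amp_g * env * stats::rnorm(m)
    }
  }

  if (phys$noise_sd_g > 0) {
    ax <- ax + stats::rnorm(n, 0, phys$noise_sd_g)
    ay <- ay + stats::rnorm(n, 0, phys$noise_sd_g)
    az <- az + stats::rnorm(n, 0, phys$noise_sd_g)
  }
  triaxial_accel(ax, ay, az, fs)
}

#' Classifier input bundle from simulated ground truth
#'
#' Builds the 10 Hz [effort_bundle()] directly from a simulation's true
#' beats, effort and movement intervals, bypassing waveform synthesis
#' and signal extraction. This is the fast path for training and
#' evaluating the stager on many nights; the extraction chain itself is
#' exercised separately on synthesized waveforms. Activity counts are
#' the analytic expectation of the per-second mean-absolute-deviation
#' formula: a quiet floor from sensor noise and respiration plus
#' `3 * amp * sqrt(2/pi)` times the within-second movement fraction.
#'
#' @param rec A `simulated_recording` (with or without waveforms).
#' @param config A [default_config()]-style list (`act_scale`, `q_min`).
#' @return An [effort_bundle()].
#' @export
simulate_bundle <- function(rec, config = default_config()) {
  stopifnot(inherits(rec, "simulated_recording"))
  nsec <- length(rec$hypnogram$labels) * rec$hypnogram$epoch_s
  ihr <- compute_ihr(rec$true_beats, fs = 10, t0 = 0, duration = nsec)
  res <- gapped_series(rec$true_effort$values[seq_len(nsec * 10)], 10)
  act1 <- rep(0.02, nsec)
  if (nrow(rec$movement_intervals) > 0) {
    burst <- 3 * rec$phys$move_amp_g * sqrt(2 / pi)
    for (j in seq_len(nrow(rec$movement_intervals))) {
      s1 <- rec$movement_intervals[j, 1]; s2 <- rec$movement_intervals[j, 2]
      secs <- max(1L, floor(s1) + 1L):min(nsec, ceiling(s2))
      frac <- pmin(secs, s2) - pmax(secs - 1, s1)
      act1[secs] <- act1[secs] + burst * pmax(frac, 0)
    }
  }
  resact <- mix_effort(res, act1, config$act_scale)
  effort_bundle(ihr, res, rep(act1, each = 10L), act1, resact)
}

#' Retime a beat series with a clock offset and rate
#'
#' Models a device clock that differs from the reference by an affine
#' map: `t' = offset + rate * t`; IBIs scale by `rate`.
#'
#' @param beats A [beat_series()].
#' @param offset Clock offset in seconds.
#' @param rate Clock rate (`> 0`).
#' @return The retimed [beat_series()]; qualities are preserved.
#' @export
inject_clock_skew <- function(beats, offset, rate) {
  stopifnot(inherits(beats, "beat_series"))
  if (rate <= 0) stop("clock rate must be positive")
  beat_series(offset + rate * beats$t, rate * beats$ibi, beats$quality)
}

#' Simulate a complete overnight recording
#'
#' Draws a hypnogram, stage-conditional heartbeats, respiratory effort
#' and movement intervals, and synthesizes the triaxial acceleration.
#' One root seed deterministically derives an independent child stream
#' per component; the streams are recorded in the result.
#'
#' @param arch A [sleep_architecture()]; default 8-h night.
#' @param phys A [physiology_params()].
#' @param fs Acceleration sampling rate (Hz).
#' @param seed Integer root seed.
#' @param accel If `FALSE`, skip waveform synthesis (hypnogram,
#'   beats, effort and movements only) for bundle-level work.
#' @return A `simulated_recording` list: `hypnogram`, `true_beats`,
#'   `true_effort`, `movement_intervals`, `accel` (or `NULL`), `seed`,
#'   `child_seeds`, `phys`.
#' @export
simulate_recording <- function(arch = default_sleep_architecture(),
                               phys = physiology_params(),
                               fs = 100, seed = 1, accel = TRUE) {
  seeds <- c(hypnogram = child_seed(seed, 1), beats = child_seed(seed, 2),
             effort = child_seed(seed, 3), movements = child_seed(seed, 4),
             accel = child_seed(seed, 5))
  hyp <- simulate_hypnogram(arch, seeds[["hypnogram"]])
  beats <- simulate_beats(hyp, phys, seeds[["beats"]])
  effort <- simulate_effort(hyp, phys, seeds[["effort"]])
  mov <- simulate_movements(hyp, phys, seeds[["movements"]])
  acc <- if (accel)
    synthesize_acceleration(beats, effort, mov, phys, fs, seeds[["accel"]])
  else NULL
  structure(list(hypnogram = hyp, true_beats = beats, true_effort = effort,
                 movement_intervals = mov, accel = acc, seed = seed,
                 child_seeds = seeds, phys = phys),
            class = "simulated_recording")
}
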