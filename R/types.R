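# Core containers shared across the pipeline. All are lightweight S3 lists
# with validating constructors; downstream code relies on the invariants
# enforced here rather than re-checking.

#' Sleep stage alphabet
#'
#' Canonical single-letter codes and display names for the four-class
#' staging task: `W` (Wake), `L` (light sleep, N1+N2), `D` (deep sleep,
#' N3), `R` (REM). The order of `stage_codes()` is the canonical class
#' order used by probability matrices and transition matrices.
#'
#' @return `stage_codes()` returns the four codes; `stage_names()` the
#'   matching display names.
#' @export
stage_codes <- function() c("W", "L", "D", "R")

#' @rdname stage_codes
#' @export
stage_names <- function() c(W = "Wake", L = "N1+N2", D = "N3", R = "REM")

#' Triaxial acceleration container
#'
#' @param x,y,z Numeric channel vectors in g, equal length.
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds (default 0).
#' @return A `triaxial_accel` object.
#' @export
triaxial_accel <- function(x, y, z, fs, t0 = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z))
  if (length(x) != length(y) || length(x) != length(z))
    stop("accelerometer channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate must be a positive scalar")
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("acceleration channels must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "triaxial_accel")
}

#' @export
length.triaxial_accel <- function(x) length(x$x)

#' @export
print.triaxial_accel <- function(x, ...) {
  cat(sprintf("<triaxial_accel> %d samples @ %g Hz (%.1f s), start %.3f s\n",
              length(x$x), x$fs, length(x$x) / x$fs, x$t0))
  invisible(x)
}

#' Sample times of a triaxial recording
#' @param accel A `triaxial_accel`.
#' @return Numeric vector of sample times in seconds.
#' @export
accel_times <- function(accel) {
  accel$t0 + (seq_along(accel$x) - 1L) / accel$fs
}

#' Heartbeat series container
#'
#' Beat localization times with inter-beat intervals and a per-beat
#' quality score. `ibi[i]` is the time to the next beat; the last beat's
#' IBI may be `NA` when no successor exists.
#'
#' @param t Strictly increasing beat times (s).
#' @param ibi Inter-beat intervals (s); defaults to `diff(t)` plus a
#'   trailing `NA`.
#' @param quality Per-beat quality in `[0, 1]`; defaults to 1.
#' @return A `beat_series` object.
#' @export
beat_series <- function(t, ibi = NULL, quality = NULL) {
  t <- as.numeric(t)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("beat times must be strictly increasing")
  if (is.null(ibi)) {
    ibi <- if (length(t) >= 2L) c(diff(t), NA_real_) else rep(NA_real_, length(t))
  }
  ibi <- as.numeric(ibi)
  if (length(ibi) != length(t)) stop("ibi must match beat times in length")
  if (any(ibi[!is.na(ibi)] <= 0)) stop("inter-beat intervals must be positive")
  n <- length(t)
  if (n >= 2L) {
    d <- t[-1] - t[-n]
    if (any(abs(ibi[-n] - d) > 1e-9))
      stop("ibi[i] must equal t[i+1] - t[i] where the next beat exists")
  }
  if (is.null(quality)) quality <- rep(1, n)
  quality <- as.numeric(quality)
  if (length(quality) != n || any(quality < 0 | quality > 1, na.rm = TRUE))
    stop("quality must be per-beat values in [0, 1]")
  structure(list(t = t, ibi = ibi, quality = quality), class = "beat_series")
}

#' @export
length.beat_series <- function(x) length(x$t)

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$t)
  if (n == 0) cat("<beat_series> empty\n")
  else cat(sprintf("<beat_series> %d beats over %.1f s, median IBI %.3f s\n",
                   n, diff(range(x$t)), stats::median(x$ibi, na.rm = TRUE)))
  invisible(x)
}

#' Uniformly sampled series with a validity mask
#'
#' @param values Numeric samples; entries under an invalid mask carry no
#'   meaning.
#' @param fs Sampling rate (Hz).
#' @param valid Logical mask, same length as `values` (default all TRUE).
#' @param t0 Time of the first sample (s).
#' @return A `gapped_series` object.
#' @export
gapped_series <- function(values, fs, valid = NULL, t0 = 0) {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop("validity mask must match values in length")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  structure(list(values = values, fs = as.numeric(fs),
                 valid = as.logical(valid), t0 = as.numeric(t0)),
            class = "gapped_series")
}

#' @export
length.gapped_series <- function(x) length(x$values)

#' @export
print.gapped_series <- function(x, ...) {
  cat(sprintf("<gapped_series> %d samples @ %g Hz, %.1f%% valid\n",
              length(x$values), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Sample times of a gapped series
#' @param x A `gapped_series`.
#' @return Numeric vector of sample times (s).
#' @export
series_times <- function(x) x$t0 + (seq_along(x$values) - 1L) / x$fs

#' Classifier input bundle
#'
#' The 10 Hz signal set fed to the sleep stager: gap-masked instantaneous
#' heart rate (`ihr`, bpm), respiratory effort (`res`), activity counts
#' (`act1hz` at 1 Hz plus its sample-and-hold 10 Hz copy `act`), and the
#' actigraphy-modified effort `resact`.
#'
#' @param ihr,res,resact `gapped_series` at 10 Hz, equal length.
#' @param act 10 Hz numeric activity (sample-and-hold upsampled), `>= 0`.
#' @param act1hz 1 Hz numeric activity counts, `>= 0`.
#' @return An `effort_bundle` object.
#' @export
effort_bundle <- function(ihr, res, act, act1hz, resact) {
  for (s in list(ihr, res, resact))
    if (!inherits(s, "gapped_series") || s$fs != 10)
      stop("ihr, res and resact must be 10 Hz gapped_series")
  n <- length(ihr$values)
  if (length(res$values) != n || length(resact$values) != n || length(act) != n)
    stop("all 10 Hz members of the bundle must share length")
  if (any(act < 0) || any(act1hz < 0)) stop("activity counts must be non-negative")
  structure(list(ihr = ihr, res = res, act = as.numeric(act),
                 act1hz = as.numeric(act1hz), resact = resact),
            class = "effort_bundle")
}

#' @export
print.effort_bundle <- function(x, ...) {
  cat(sprintf("<effort_bundle> %d samples @ 10 Hz (%.1f min), IHR %.1f%% valid\n",
              length(x$ihr$values), length(x$ihr$values) / 600,
              100 * mean(x$ihr$valid)))
  invisible(x)
}

#' Per-epoch stage label sequence
#'
#' One label per 30-s epoch over the four-class alphabet (or a merged
#' alphabet produced by [merge_classes()]), optionally with per-epoch
#' class probabilities.
#'
#' @param labels Character vector of stage codes.
#' @param probs Optional numeric matrix, one row per epoch, columns named
#'   by class; rows must sum to 1 and the argmax must agree with `labels`.
#' @param alphabet Allowed codes (default the four-class alphabet).
#' @param epoch_s Epoch length in seconds (default 30).
#' @param flags Optional logical vector marking context-only epochs.
#' @return A `stage_sequence` object.
#' @export
stage_sequence <- function(labels, probs = NULL, alphabet = stage_codes(),
                           epoch_s = 30, flags = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), alphabet)
  if (length(bad) > 0)
    stop(sprintf("unknown stage label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(alphabet, collapse = ", ")))
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    if (nrow(probs) != length(labels))
      stop("probability matrix must have one row per epoch")
    if (is.null(colnames(probs)) || !setequal(colnames(probs), alphabet))
      stop("probability columns must be named by the class alphabet")
    probs <- probs[, alphabet, drop = FALSE]
    if (length(labels) > 0) {
      if (any(abs(rowSums(probs) - 1) > 1e-6))
        stop("probability rows must sum to 1")
      am <- alphabet[max.col(probs, ties.method = "first")]
      agree <- am == labels
      # allow exact ties to disagree with the label
      tied <- apply(probs, 1, function(p) sum(p == max(p)) > 1)
      if (any(!agree & !tied))
        stop("label must be the argmax of the probability row")
    }
  }
  if (!is.null(flags) && length(flags) != length(labels))
    stop("flags must match labels in length")
  structure(list(labels = labels, probs = probs, alphabet = alphabet,
                 epoch_s = epoch_s, flags = flags),
            class = "stage_sequence")
}

#' @export
length.stage_sequence <- function(x) length(x$labels)

#' @export
print.stage_sequence <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<stage_sequence> %d x %g-s epochs (%.1f min)\n",
              n, x$epoch_s, n * x$epoch_s / 60))
  if (n > 0) print(table(factor(x$labels, levels = x$alphabet)))
  invisible(x)
}

#' Clock model linking two device time bases
#'
#' Maps a device time `t` onto the reference base as `o + r * t`.
#'
#' @param offset Clock offset `o` in seconds.
#' @param rate Clock rate `r` (dimensionless, `> 0`); crystal clocks sit
#'   within about 1e-3 of 1.
#' @return A `clock_model` object.
#' @export
clock_model <- function(offset = 0, rate = 1) {
  if (!is.numeric(rate) || rate <= 0) stop("clock rate must be positive")
  structure(list(offset = as.numeric(offset), rate = as.numeric(rate)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> offset %.4f s, rate %.7f\n", x$offset, x$rate))
  invisible(x)
}

# internal: validate a row-stochastic matrix, naming the offending row
check_stochastic <- function(m, what = "transition matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be square", what))
  if (any(m < 0))
    stop(sprintf("%s has negative entries", what))
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0)
    stop(sprintf("%s row %d sums to %.12g, not 1", what, off[1], rs[off[1]]))
  invisible(TRUE)
}
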