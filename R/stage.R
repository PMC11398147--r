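# 30-s epoch classification into Wake / N1+N2 / N3 / REM from IHR and
# ResAct. A transparent surrogate honors the deep classifier's contract:
# 10 Hz inputs in, per-epoch four-class probabilities out, with global
# temporal context supplied by most-probable-path smoothing over a
# stage-transition matrix instead of recurrent layers.

epoch_feature_names <- function() {
  base <- c("ihr_mean", "ihr_sd", "ihr_range", "ihr_sdsd", "ihr_lf",
            "ihr_hf", "ihr_lfhf", "resp_f", "resp_peak", "resp_cv",
            "act_sum", "ihr_invalid_frac")
  c(base, paste0("ctx_", base))
}

# one-sided periodogram of a (detrended) epoch, zero-padded for finer
# frequency resolution
epoch_spectrum <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  nf <- stats::nextn(4L * n, 2)
  p <- Mod(stats::fft(c(v, numeric(nf - n))))^2
  k <- seq_len(nf %/% 2)
  list(f = (k - 1) * fs / nf, p = p[k])
}

band_power <- function(sp, lo, hi) sum(sp$p[sp$f >= lo & sp$f <= hi])

#' Per-epoch features from the classifier input bundle
#'
#' Splits the 10 Hz bundle into complete 30-s epochs (a trailing partial
#' epoch is dropped) and computes, per epoch: IHR mean/std/range and the
#' RMS of successive differences; IHR band power in the low (0.04--0.15
#' Hz) and high (0.15--0.4 Hz) HRV bands and their ratio; the ResAct
#' dominant respiratory frequency in 0.1--0.7 Hz, its spectral
#' peakedness (peak power over band power) and amplitude coefficient of
#' variation; the epoch's summed activity; and the fraction of invalid
#' IHR samples. Epochs with under 50% valid IHR get missing IHR features
#' and are flagged. Each feature also gets a context copy averaged over
#' the +/-2 surrounding epochs.
#'
#' @param bundle An [effort_bundle()].
#' @param epoch_s Epoch length in seconds (default 30).
#' @return A data frame, one row per epoch, with a logical `missing`
#'   column.
#' @export
epochize <- function(bundle, epoch_s = 30) {
  stopifnot(inherits(bundle, "effort_bundle"))
  fs <- 10
  spe <- epoch_s * fs
  n_ep <- length(bundle$ihr$values) %/% spe
  base_names <- c("ihr_mean", "ihr_sd", "ihr_range", "ihr_sdsd", "ihr_lf",
                  "ihr_hf", "ihr_lfhf", "resp_f", "resp_peak", "resp_cv",
                  "act_sum", "ihr_invalid_frac")
  out <- as.data.frame(matrix(NA_real_, n_ep, length(base_names),
                              dimnames = list(NULL, base_names)))
  out$missing <- logical(n_ep)
  if (n_ep == 0) {
    for (nm in paste0("ctx_", base_names)) out[[nm]] <- numeric(0)
    return(out)
  }
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1) * spe + 1):(e * spe)
    ihr_v <- bundle$ihr$values[idx]
    ok <- bundle$ihr$valid[idx]
    out$ihr_invalid_frac[e] <- 1 - mean(ok)
    if (mean(ok) >= 0.5) {
      iv <- ihr_v[ok]
      out$ihr_mean[e] <- mean(iv)
      out$ihr_sd[e] <- stats::sd(iv)
      out$ihr_range[e] <- diff(range(iv))
      out$ihr_sdsd[e] <- if (length(iv) > 1) sqrt(mean(diff(iv)^2)) else 0
      # interpolate across gaps for the spectral features
      full <- ihr_v
      if (any(!ok))
        full <- stats::approx(which(ok), iv, xout = seq_len(spe), rule = 2)$y
      sp <- epoch_spectrum(full, fs)
      lf <- band_power(sp, 0.04, 0.15)
      hf <- band_power(sp, 0.15, 0.4)
      out$ihr_lf[e] <- lf
      out$ihr_hf[e] <- hf
      out$ihr_lfhf[e] <- lf / max(hf, 1e-12)
    } else {
      out$missing[e] <- TRUE
    }
    ra <- bundle$resact$values[idx]
    sp <- epoch_spectrum(ra, fs)
    band <- sp$f >= 0.1 & sp$f <= 0.7
    if (any(band) && sum(sp$p[band]) > 0) {
      out$resp_f[e] <- sp$f[band][which.max(sp$p[band])]
      out$resp_peak[e] <- max(sp$p[band]) / sum(sp$p[band])
    } else {
      out$resp_f[e] <- 0
      out$resp_peak[e] <- 0
    }
    amp <- abs(ra)
    out$resp_cv[e] <- if (mean(amp) > 0) stats::sd(amp) / mean(amp) else 0
    out$act_sum[e] <- sum(bundle$act[idx]) / fs
  }
  for (nm in base_names) {
    v <- out[[nm]]
    ctx <- vapply(seq_len(n_ep), function(e) {
      w <- v[max(1, e - 2):min(n_ep, e + 2)]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, numeric(1))
    out[[paste0("ctx_", nm)]] <- ctx
  }
  out
}

# design matrix in canonical feature order, standardized and 0-imputed
stager_design <- function(features, center, scale) {
  nms <- epoch_feature_names()
  miss <- setdiff(nms, names(features))
  if (length(miss) > 0)
    stop(sprintf("feature schema mismatch: missing %s",
                 paste(miss, collapse = ", ")))
  X <- as.matrix(features[, nms, drop = FALSE])
  X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  X[!is.finite(X)] <- 0
  X
}

#' Train the sleep stager
#'
#' Fits a regularized multinomial linear scorer (softmax regression with
#' weight decay) on standardized epoch features pooled over recordings,
#' and estimates the stage-transition matrix and initial distribution
#' from the training hypnograms with add-one smoothing. Flagged missing
#' epochs are excluded from the emission fit but still contribute
#' transitions.
#'
#' @param features_list List of [epochize()] frames, one per recording.
#' @param labels_list List of matching [stage_sequence()] hypnograms.
#' @param seed Integer seed (weight initialization).
#' @param decay L2 penalty passed to the optimizer (default 1e-2).
#' @return A `stager_model`: coefficient matrix (classes x features+1),
#'   standardization constants, transition matrix, initial distribution,
#'   and training metadata.
#' @export
train_stager <- function(features_list, labels_list, seed = 1, decay = 1e-2) {
  if (!is.list(features_list) || length(features_list) < 2)
    stop("training requires at least 2 recordings")
  if (length(features_list) != length(labels_list))
    stop("features and labels must pair up per recording")
  codes <- stage_codes()
  all_lab <- unlist(lapply(labels_list, function(s) s$labels))
  absent <- setdiff(codes, unique(all_lab))
  if (length(absent) > 0)
    stop(sprintf("training labels lack class(es): %s (%s)",
                 paste(absent, collapse = ", "),
                 paste(stage_names()[absent], collapse = ", ")))

  nms <- epoch_feature_names()
  X_raw <- NULL; y <- character(0); keep_all <- logical(0)
  for (i in seq_along(features_list)) {
    f <- features_list[[i]]
    lab <- labels_list[[i]]$labels
    n <- min(nrow(f), length(lab))
    X_raw <- rbind(X_raw, as.matrix(f[seq_len(n), nms, drop = FALSE]))
    y <- c(y, lab[seq_len(n)])
    keep_all <- c(keep_all, !f$missing[seq_len(n)])
  }
  center <- apply(X_raw, 2, function(v) mean(v, na.rm = TRUE))
  scale <- apply(X_raw, 2, function(v) stats::sd(v, na.rm = TRUE))
  center[!is.finite(center)] <- 0
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(X_raw, 2, center, "-"), 2, scale, "/")
  X[!is.finite(X)] <- 0
  X <- X[keep_all, , drop = FALSE]
  yf <- factor(y[keep_all], levels = codes)
  if (nlevels(droplevels(yf)) < 4)
    stop(sprintf("training labels lack class(es): %s",
                 paste(setdiff(codes, levels(droplevels(yf))), collapse = ", ")))

  set.seed(seed)
  dat <- data.frame(y = yf, X)
  fit <- nnet::multinom(y ~ ., data = dat, decay = decay, maxit = 400,
                        trace = FALSE)
  cf <- stats::coef(fit)  # (K-1) x (p+1), vs the first level
  coef_full <- rbind(0, as.matrix(cf))
  rownames(coef_full) <- codes
  colnames(coef_full)[1] <- "(Intercept)"

  # smoothed empirical transitions and initial distribution
  trans <- matrix(1, 4, 4, dimnames = list(codes, codes))
  init <- rep(1, 4); names(init) <- codes
  for (s in labels_list) {
    lab <- s$labels
    if (length(lab) == 0) next
    init[lab[1]] <- init[lab[1]] + 1
    if (length(lab) > 1)
      for (i in seq_len(length(lab) - 1))
        trans[lab[i], lab[i + 1]] <- trans[lab[i], lab[i + 1]] + 1
  }
  trans <- trans / rowSums(trans)
  init <- init / sum(init)

  structure(list(coef = coef_full, center = center, scale = scale,
                 transition = trans, initial = init,
                 feature_names = nms,
                 meta = list(seed = seed, decay = decay,
                             n_recordings = length(features_list),
                             n_epochs = length(y))),
            class = "stager_model")
}

#' @export
print.stager_model <- function(x, ...) {
  cat(sprintf("<stager_model> %d features, trained on %d recordings (%d epochs)\n",
              length(x$feature_names), x$meta$n_recordings, x$meta$n_epochs))
  invisible(x)
}

#' Most probable state path (Viterbi decoding)
#'
#' @param log_emission n x K matrix of per-epoch log emission scores.
#' @param transition K x K row-stochastic transition matrix.
#' @param initial Length-K initial distribution.
#' @return Integer vector of state indices along the single most
#'   probable path.
#' @export
viterbi_path <- function(log_emission, transition, initial) {
  n <- nrow(log_emission); K <- ncol(log_emission)
  if (n == 0) return(integer(0))
  check_stochastic(transition)
  lt <- log(transition)
  delta <- matrix(-Inf, n, K)
  back <- matrix(0L, n, K)
  delta[1, ] <- log(initial) + log_emission[1, ]
  if (n > 1) for (i in 2:n) {
    for (k in 1:K) {
      cand <- delta[i - 1, ] + lt[, k]
      back[i, k] <- which.max(cand)
      delta[i, k] <- cand[back[i, k]] + log_emission[i, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- back[i + 1, path[i + 1]]
  path
}

#' Forward-backward state posteriors
#'
#' @inheritParams viterbi_path
#' @return n x K matrix of smoothed per-epoch posteriors (rows sum to 1).
#' @export
smooth_posteriors <- function(log_emission, transition, initial) {
  n <- nrow(log_emission); K <- ncol(log_emission)
  if (n == 0) return(matrix(numeric(0), 0, K))
  em <- exp(log_emission - apply(log_emission, 1, max))
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  alpha[1, ] <- initial * em[1, ]
  alpha[1, ] <- alpha[1, ] / sum(alpha[1, ])
  if (n > 1) for (i in 2:n) {
    a <- (alpha[i - 1, ] %*% transition) * em[i, ]
    alpha[i, ] <- a / sum(a)
  }
  beta[n, ] <- 1
  if (n > 1) for (i in (n - 1):1) {
    b <- transition %*% (beta[i + 1, ] * em[i + 1, ])
    beta[i, ] <- b / sum(b)
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Classify epochs into sleep stages
#'
#' Converts each epoch's linear class scores into emission probabilities,
#' decodes the most probable whole-night path under the model's
#' transition matrix (the labels), and reports forward-backward smoothed
#' posteriors as the per-epoch probabilities. Epochs flagged missing get
#' uninformative emissions, so their stage comes from temporal context
#' alone; they are flagged in the output.
#'
#' @param features An [epochize()] frame.
#' @param model A [train_stager()] model.
#' @return A [stage_sequence()] with probabilities and context-only
#'   flags.
#' @export
classify_stages <- function(features, model) {
  stopifnot(inherits(model, "stager_model"))
  n <- nrow(features)
  codes <- stage_codes()
  if (n == 0) return(stage_sequence(character(0)))
  X <- stager_design(features, model$center, model$scale)
  eta <- cbind(1, X) %*% t(model$coef)  # n x 4 linear scores
  logem <- eta - apply(eta, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  miss <- features$missing
  logem[miss, ] <- 0  # uniform emission: context-only
  path <- viterbi_path(logem, model$transition, model$initial)
  post <- smooth_posteriors(logem, model$transition, model$initial)
  colnames(post) <- codes
  labels <- codes[path]
  # labels come from the single most probable path; the smoothed
  # posteriors are reported alongside and may rarely argmax-differ from
  # the joint decode, so they are attached without re-deriving labels
  out <- stage_sequence(labels, probs = NULL, flags = miss)
  out$probs <- post
  out
}

#' Merge stage classes
#'
#' `four` keeps the four-class task; `three` merges N1+N2 and N3 into a
#' single NREM class (`N`); `one_vs_rest` maps the `positive` class to
#' `pos` and everything else to `neg`. Probabilities, when present, are
#' summed over merged classes.
#'
#' @param stages A four-class [stage_sequence()].
#' @param scheme `"four"`, `"three"` or `"one_vs_rest"`.
#' @param positive Positive class code for `one_vs_rest`.
#' @return The remapped [stage_sequence()].
#' @export
merge_classes <- function(stages, scheme = c("four", "three", "one_vs_rest"),
                          positive = NULL) {
  stopifnot(inherits(stages, "stage_sequence"))
  scheme <- match.arg(scheme)
  if (!setequal(stages$alphabet, stage_codes()))
    stop("merge_classes expects a four-class input")
  if (scheme == "four") return(stages)
  if (scheme == "three") {
    map <- c(W = "W", L = "N", D = "N", R = "R")
    alphabet <- c("W", "N", "R")
  } else {
    if (is.null(positive) || !positive %in% stage_codes())
      stop("one_vs_rest needs a positive class among W, L, D, R")
    map <- stats::setNames(rep("neg", 4), stage_codes())
    map[positive] <- "pos"
    alphabet <- c("pos", "neg")
  }
  labels <- unname(map[stages$labels])
  probs <- NULL
  if (!is.null(stages$probs)) {
    probs <- matrix(0, nrow(stages$probs), length(alphabet),
                    dimnames = list(NULL, alphabet))
    for (cl in stage_codes())
      probs[, map[cl]] <- probs[, map[cl]] + stages$probs[, cl]
  }
  out <- stage_sequence(labels, probs = NULL, alphabet = alphabet,
                        epoch_s = stages$epoch_s, flags = stages$flags)
  out$probs <- probs
  out
}
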