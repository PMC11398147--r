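# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# per-second activity counts, literal two-pass evaluation of the formula
oracle_activity <- function(x, y, z, fs) {
  nsec <- length(x) %/% fs
  out <- numeric(nsec)
  for (s in seq_len(nsec)) {
    idx <- ((s - 1) * fs + 1):(s * fs)
    acc <- 0
    for (ch in list(x, y, z)) {
      v <- ch[idx]
      m <- sum(v) / length(v)
      acc <- acc + sum(abs(v - m)) / length(v)
    }
    out[s] <- acc
  }
  out
}

# Cohen's kappa straight from the definition, scalar loops only
oracle_kappa <- function(counts) {
  n <- sum(counts)
  po <- 0
  for (i in seq_len(nrow(counts))) po <- po + counts[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(counts)))
    pe <- pe + sum(counts[i, ]) * sum(counts[, i])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# exhaustive gap-tolerant interval finder: all candidate (i, j) windows
# bounded by target epochs, admissible if no interior non-target run
# exceeds M, keep the maximal ones
oracle_intervals <- function(labels, target, M) {
  hits <- which(labels == target)
  if (length(hits) == 0) return(matrix(integer(0), ncol = 2))
  adm <- NULL
  for (i in hits) for (j in hits[hits >= i]) {
    seg <- labels[i:j] != target
    runs <- rle(seg)
    if (all(runs$lengths[runs$values] <= M) || !any(runs$values))
      adm <- rbind(adm, c(i, j))
  }
  keep <- rep(TRUE, nrow(adm))
  for (k in seq_len(nrow(adm))) for (l in seq_len(nrow(adm))) {
    if (k != l && adm[l, 1] <= adm[k, 1] && adm[k, 2] <= adm[l, 2] &&
        !(adm[l, 1] == adm[k, 1] && adm[l, 2] == adm[k, 2]))
      keep[k] <- FALSE
  }
  out <- adm[keep, , drop = FALSE]
  out[order(out[, 1]), , drop = FALSE]
}

# exhaustive most-probable-path search over all K^n state sequences
oracle_viterbi <- function(log_emission, transition, initial) {
  n <- nrow(log_emission)
  K <- ncol(log_emission)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    sc <- log(initial[p[1]]) + log_emission[1, p[1]]
    if (n > 1) for (i in 2:n)
      sc <- sc + log(transition[p[i - 1], p[i]]) + log_emission[i, p[i]]
    if (sc > best) { best <- sc; best_path <- p }
  }
  unname(best_path)
}

# small movement-free recording shared by extraction tests (cached per run)
.clean_rec_cache <- new.env()
get_clean_recording <- function() {
  if (is.null(.clean_rec_cache$rec)) {
    arch <- default_sleep_architecture(n_epochs = 10)
    phys <- physiology_params(
      move_rate_per_min = c(W = 0, L = 0, D = 0, R = 0))
    .clean_rec_cache$rec <- simulate_recording(arch, phys, seed = 4242)
  }
  .clean_rec_cache$rec
}
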