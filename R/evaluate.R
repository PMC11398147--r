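# Hypnogram agreement and sleep-metric evaluation: confusion matrices
# with reference-row percentages, Cohen's kappa, one-vs-rest metrics,
# cohort summaries, Bland-Altman limits of agreement, gap-tolerant stage
# intervals, and cohort factor statistics with FDR control.

#' Confusion matrix between two stage sequences
#'
#' Rows are the reference, columns the estimate; percentages are each
#' cell relative to its reference-row total.
#'
#' @param ref,est [stage_sequence()]s of equal length over the same
#'   alphabet.
#' @param order Class display order (default the sequences' alphabet).
#' @return A `confusion_matrix`: integer `counts`, exact `row_pct`, and
#'   `total`.
#' @export
confusion <- function(ref, est, order = NULL) {
  stopifnot(inherits(ref, "stage_sequence"), inherits(est, "stage_sequence"))
  if (length(ref$labels) != length(est$labels))
    stop(sprintf("length mismatch: reference %d vs estimate %d epochs",
                 length(ref$labels), length(est$labels)))
  if (!setequal(ref$alphabet, est$alphabet))
    stop("reference and estimate must share a class alphabet")
  if (is.null(order)) order <- ref$alphabet
  confusion_from_counts(table(factor(ref$labels, levels = order),
                              factor(est$labels, levels = order)))
}

#' Build a confusion matrix from a count table
#'
#' @param counts Square matrix of non-negative epoch counts, reference
#'   rows by estimate columns.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(unclass(counts))
  storage.mode(counts) <- "double"
  if (nrow(counts) != ncol(counts) || any(counts < 0))
    stop("counts must be a square non-negative matrix")
  rs <- rowSums(counts)
  row_pct <- counts / ifelse(rs == 0, NA, rs) * 100
  structure(list(counts = counts, row_pct = row_pct, total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d epochs\n", x$total))
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$row_pct),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. When both raters use a
#' single identical class (`p_e = 1`, `p_o = 1`) the value is 1 with a
#' `degenerate` attribute set.
#'
#' @param cm A `confusion_matrix`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) stop("empty confusion matrix")
  n <- cm$total
  po <- sum(diag(cm$counts)) / n
  pe <- sum(rowSums(cm$counts) * colSums(cm$counts)) / n^2
  if (abs(1 - pe) < 1e-15) {
    k <- if (po >= 1 - 1e-15) 1 else 0
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest binary metrics
#'
#' Collapses the matrix to `positive` vs rest and reports sensitivity,
#' specificity, PPV and accuracy in percent. Undefined denominators give
#' `NA`, not zero.
#'
#' @param cm A `confusion_matrix` (any number of classes).
#' @param positive Positive class name (must be among the row names).
#' @return Named numeric: `sensitivity`, `specificity`, `ppv`,
#'   `accuracy` (all %).
#' @export
binary_metrics <- function(cm, positive) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cls <- rownames(cm$counts)
  if (!positive %in% cls) stop(sprintf("unknown positive class '%s'", positive))
  p <- cls == positive
  tp <- sum(cm$counts[p, p])
  fn <- sum(cm$counts[p, !p])
  fp <- sum(cm$counts[!p, p])
  tn <- sum(cm$counts[!p, !p])
  pct <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  c(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp), accuracy = pct(tp + tn, tp + fn + fp + tn))
}

#' Per-recording agreement battery
#'
#' Computes the full task set for one recording pair: four-class kappa
#' and accuracy, three-class (NREM-merged) kappa and accuracy, and
#' kappa/accuracy/sensitivity/specificity/PPV for each one-vs-rest task.
#'
#' @param ref,est Four-class [stage_sequence()]s.
#' @return A one-row data frame.
#' @export
agreement_battery <- function(ref, est) {
  cm4 <- confusion(ref, est)
  cm3 <- confusion(merge_classes(ref, "three"), merge_classes(est, "three"))
  out <- data.frame(kappa4 = cohens_kappa(cm4),
                    acc4 = sum(diag(cm4$counts)) / cm4$total * 100,
                    kappa3 = cohens_kappa(cm3),
                    acc3 = sum(diag(cm3$counts)) / cm3$total * 100)
  for (cl in stage_codes()) {
    cmb <- confusion(merge_classes(ref, "one_vs_rest", positive = cl),
                     merge_classes(est, "one_vs_rest", positive = cl))
    bm <- binary_metrics(cmb, "pos")
    kb <- cohens_kappa(cmb)
    out[[paste0("kappa_", cl)]] <- as.numeric(kb)
    out[[paste0("acc_", cl)]] <- bm[["accuracy"]]
    out[[paste0("sens_", cl)]] <- bm[["sensitivity"]]
    out[[paste0("spec_", cl)]] <- bm[["specificity"]]
    out[[paste0("ppv_", cl)]] <- bm[["ppv"]]
  }
  out
}

#' Cohort summary of a per-recording statistic
#'
#' Reports both the mean +/- SD and the median with quartiles, choosing
#' the primary presentation by a Shapiro-Wilk normality test at
#' alpha = 0.05.
#'
#' @param values Numeric vector, at least 3 values.
#' @return List: `mean`, `sd`, `median`, `q1`, `q3`, `normal`,
#'   `primary` (`"mean_sd"` or `"median_iqr"`).
#' @export
cohort_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("cohort summary needs at least 3 values")
  normal <- if (length(unique(values)) == 1) TRUE
  else stats::shapiro.test(values)$p.value >= 0.05
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  list(mean = mean(values), sd = stats::sd(values),
       median = q[2], q1 = q[1], q3 = q[3], normal = normal,
       primary = if (normal) "mean_sd" else "median_iqr")
}

#' Sleep metrics from a hypnogram
#'
#' Epochs are 0.5 min. Sleep onset is the first non-Wake epoch; sleep
#' latency is the onset index times 0.5 min; TST counts non-Wake
#' epochs; WASO counts Wake epochs after onset; stage-R latency runs
#' from onset to the first REM epoch; sleep efficiency is TST over total
#' recording time. Time in stage and percentage of TST are reported per
#' stage (including a Wake row expressed relative to TST). With no sleep
#' epochs the latencies and WASO are `NA` and TST is 0.
#'
#' @param hyp A four-class [stage_sequence()].
#' @return A one-row data frame of metrics (minutes and percent).
#' @export
sleep_metrics <- function(hyp) {
  stopifnot(inherits(hyp, "stage_sequence"))
  lab <- hyp$labels
  n <- length(lab)
  if (n == 0) stop("empty hypnogram")
  ep_min <- hyp$epoch_s / 60
  sleep <- lab != "W"
  tst <- sum(sleep) * ep_min
  trt <- n * ep_min
  onset <- if (any(sleep)) which(sleep)[1] else NA_integer_
  latency <- if (is.na(onset)) NA_real_ else (onset - 1) * ep_min
  waso <- if (is.na(onset)) NA_real_ else sum(lab[onset:n] == "W") * ep_min
  first_r <- if (any(lab == "R")) which(lab == "R")[1] else NA_integer_
  r_latency <- if (is.na(onset) || is.na(first_r)) NA_real_
  else (first_r - onset) * ep_min
  tis <- vapply(stage_codes(), function(cl) sum(lab == cl) * ep_min, numeric(1))
  pct_tst <- if (tst > 0) tis / tst * 100
  else stats::setNames(rep(NA_real_, 4), stage_codes())
  data.frame(tst_min = tst, sleep_latency_min = latency, waso_min = waso,
             r_latency_min = r_latency, sleep_efficiency_pct = tst / trt * 100,
             time_wake_min = tis[["W"]], time_n12_min = tis[["L"]],
             time_n3_min = tis[["D"]], time_rem_min = tis[["R"]],
             pct_tst_wake = pct_tst[["W"]], pct_tst_n12 = pct_tst[["L"]],
             pct_tst_n3 = pct_tst[["D"]], pct_tst_rem = pct_tst[["R"]])
}

#' Bland-Altman summary of paired per-recording metrics
#'
#' Errors are `est - ref`. Reports the error median and quartiles plus
#' the 95% limits of agreement `mean(e) +/- 1.96 * sd(e)` (sample SD).
#'
#' @param est,ref Paired numeric vectors (at least 3 complete pairs).
#' @return List: `median`, `q1`, `q3`, `mean`, `sd`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref)) stop("est and ref must pair up")
  ok <- !is.na(est) & !is.na(ref)
  if (sum(ok) < 3) stop("Bland-Altman needs at least 3 complete pairs")
  e <- est[ok] - ref[ok]
  q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
  m <- mean(e); s <- stats::sd(e)
  list(median = q[2], q1 = q[1], q3 = q[3], mean = m, sd = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s, n = sum(ok))
}

#' Gap-tolerant stage intervals
#'
#' The maximal intervals in which `stage` occurs without being
#' interrupted by a run of more than `M` non-target epochs: target runs
#' whose separating gaps are `<= M` epochs are merged; intervals start
#' and end on target epochs.
#'
#' @param hyp A [stage_sequence()].
#' @param stage Target class code.
#' @param M Gap tolerance in epochs (`>= 0`); the interval analysis of
#'   overnight REM/N3 periods conventionally uses M = 20 (10 min).
#' @return A `stage_interval_set`: `stage`, `M`, and an `intervals`
#'   matrix of 1-based `(start, end)` epoch indices (inclusive).
#' @export
stage_intervals <- function(hyp, stage, M = 20) {
  stopifnot(inherits(hyp, "stage_sequence"))
  if (M < 0 || M != round(M)) stop("M must be a non-negative integer")
  hits <- which(hyp$labels == stage)
  iv <- if (length(hits) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    starts <- hits[c(TRUE, diff(hits) > M + 1)]
    ends <- hits[c(diff(hits) > M + 1, TRUE)]
    cbind(starts, ends)
  }
  dimnames(iv) <- list(NULL, c("start", "end"))
  structure(list(stage = stage, M = M, intervals = iv,
                 n_epochs = length(hyp$labels)),
            class = "stage_interval_set")
}

#' @export
print.stage_interval_set <- function(x, ...) {
  cat(sprintf("<stage_interval_set> stage %s, M = %d: %d interval(s)\n",
              x$stage, x$M, nrow(x$intervals)))
  if (nrow(x$intervals) > 0) print(x$intervals)
  invisible(x)
}

#' Match reference and estimated stage intervals
#'
#' Two intervals match when they share at least one epoch. Reports how
#' many reference intervals are overlapped by at least one estimate,
#' which estimate intervals have no reference overlap, and a one-to-one
#' pairing by greatest shared epoch count (ties broken by the earliest
#' reference, then earliest estimate interval).
#'
#' @param ref,est `stage_interval_set`s for the same stage and epoch
#'   grid.
#' @return List: `n_ref`, `n_est`, `n_ref_matched`, `unmatched_ref`,
#'   `unmatched_est` (interval row indices), and `pairs` (matrix of
#'   `ref`, `est`, `shared`).
#' @export
match_intervals <- function(ref, est) {
  stopifnot(inherits(ref, "stage_interval_set"),
            inherits(est, "stage_interval_set"))
  if (!identical(ref$stage, est$stage))
    stop("interval sets must target the same stage")
  ri <- ref$intervals; ei <- est$intervals
  nr <- nrow(ri); ne <- nrow(ei)
  shared <- matrix(0L, nr, ne)
  if (nr > 0 && ne > 0)
    for (i in seq_len(nr)) for (j in seq_len(ne))
      shared[i, j] <- max(0L, min(ri[i, 2], ei[j, 2]) -
                            max(ri[i, 1], ei[j, 1]) + 1L)
  ref_matched <- if (nr > 0) apply(shared > 0, 1, any) else logical(0)
  est_matched <- if (ne > 0) apply(shared > 0, 2, any) else logical(0)
  # one-to-one greedy pairing: greatest shared epochs, earliest-first ties
  pairs <- NULL
  if (nr > 0 && ne > 0) {
    cand <- which(shared > 0, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(-shared[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_r <- logical(nr); used_e <- logical(ne)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_r[i] && !used_e[j]) {
          pairs <- rbind(pairs, c(ref = i, est = j, shared = shared[i, j]))
          used_r[i] <- TRUE; used_e[j] <- TRUE
        }
      }
    }
  }
  list(n_ref = nr, n_est = ne, n_ref_matched = sum(ref_matched),
       unmatched_ref = which(!ref_matched), unmatched_est = which(!est_matched),
       pairs = pairs)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate control applied jointly to a family of
#' p-values.
#'
#' @param p Numeric vector of raw p-values.
#' @param fdr Acceptable false discovery rate (default 0.05).
#' @return List: `p_adj` (BH-adjusted p-values) and `significant`.
#' @export
fdr_flags <- function(p, fdr = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = p_adj <= fdr)
}

#' Influence of cohort factors on staging performance
#'
#' Binary factors (e.g. sex, disorder presence) are tested against the
#' per-recording kappas with a two-sided Mann-Whitney U test (exact for
#' tie-free groups of up to 8, normal approximation with tie correction
#' otherwise); continuous factors (e.g. age, BMI) with Spearman's rank
#' correlation. All p-values are jointly Benjamini-Hochberg adjusted and
#' flagged at the given false discovery rate.
#'
#' @param kappas Per-recording agreement values.
#' @param binary_factors Named list/data.frame of logical vectors.
#' @param continuous_factors Named list/data.frame of numeric vectors.
#' @param fdr Acceptable false discovery rate (default 0.05).
#' @return A data frame: factor, type, statistic (`rho` for continuous),
#'   `p`, `p_adj`, `significant`.
#' @export
factor_influence <- function(kappas, binary_factors = list(),
                             continuous_factors = list(), fdr = 0.05) {
  rows <- list()
  for (nm in names(binary_factors)) {
    f <- as.logical(binary_factors[[nm]])
    a <- kappas[f & !is.na(f)]; b <- kappas[!f & !is.na(f)]
    if (length(a) == 0 || length(b) == 0) {
      warning(sprintf("factor '%s' has an empty group; skipped", nm))
      next
    }
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      factor = nm, type = "binary", statistic = unname(wt$statistic),
      p = wt$p.value)
  }
  for (nm in names(continuous_factors)) {
    x <- as.numeric(continuous_factors[[nm]])
    ok <- !is.na(x) & !is.na(kappas)
    ct <- suppressWarnings(stats::cor.test(x[ok], kappas[ok],
                                           method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(
      factor = nm, type = "continuous", statistic = unname(ct$estimate),
      p = ct$p.value)
  }
  if (length(rows) == 0)
    return(data.frame(factor = character(0), type = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  fl <- fdr_flags(out$p, fdr)
  out$p_adj <- fl$p_adj
  out$significant <- fl$significant
  rownames(out) <- NULL
  out
}
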