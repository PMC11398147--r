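# Columnar text formats for every pipeline artifact, a validated
# key-value configuration, and lossless round-trips. All files are
# whitespace-separated with a header line; values are written at full
# double precision.

pipeline_version <- function() {
  paste0("accelsleep/", as.character(utils::packageVersion("accelsleep")))
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_columns <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

read_columns <- function(path, required) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df
}

#' Read and write accelerometer files
#'
#' Columnar text with header `t_s, x_g, y_g, z_g`. On read, timestamps
#' must be strictly increasing (the first offending row is named), all
#' values finite, and the rate inferred from the median time step must
#' match any rate recorded in the file header within 1%.
#'
#' @param path File path.
#' @param fs Expected sampling rate (Hz); `NULL` infers it from the
#'   timestamps.
#' @return `read_accel()` returns a [triaxial_accel()];
#'   `write_accel()` invisibly returns the path.
#' @export
read_accel <- function(path, fs = NULL) {
  df <- read_columns(path, c("t_s", "x_g", "y_g", "z_g"))
  if (nrow(df) < 2) stop(sprintf("%s: need at least 2 samples", path))
  dt <- diff(df$t_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0)
    stop(sprintf("%s: non-monotone timestamp at row %d", path, bad[1] + 1L))
  if (any(!is.finite(as.matrix(df[c("x_g", "y_g", "z_g")]))))
    stop(sprintf("%s: non-finite acceleration values", path))
  fs_inferred <- 1 / stats::median(dt)
  if (!is.null(fs) && abs(fs_inferred - fs) / fs > 0.01)
    stop(sprintf("%s: inferred rate %.3f Hz does not match declared %.3f Hz",
                 path, fs_inferred, fs))
  triaxial_accel(df$x_g, df$y_g, df$z_g, fs = fs %||% fs_inferred,
                 t0 = df$t_s[1])
}

#' @rdname read_accel
#' @param accel A [triaxial_accel()] to write.
#' @param seed Optional root seed recorded in the file header.
#' @export
write_accel <- function(accel, path, seed = NULL) {
  stopifnot(inherits(accel, "triaxial_accel"))
  write_columns(
    data.frame(t_s = accel_times(accel), x_g = accel$x, y_g = accel$y,
               z_g = accel$z),
    path, meta = c(pipeline_version(),
                   if (!is.null(seed)) paste("seed", seed),
                   paste("fs_hz", accel$fs)))
}

#' Read and write hypnogram epoch files
#'
#' Rows of `epoch_index` (contiguous from 0) and `stage` over the
#' alphabet `W, L, D, R`; estimated hypnograms may carry per-class
#' probability columns `p_W, p_L, p_D, p_R`.
#'
#' @param path File path.
#' @return `read_hypnogram()` returns a [stage_sequence()].
#' @export
read_hypnogram <- function(path) {
  df <- read_columns(path, c("epoch_index", "stage"))
  if (nrow(df) > 0 && !identical(as.integer(df$epoch_index),
                                 seq_len(nrow(df)) - 1L))
    stop(sprintf("%s: epoch_index must be contiguous from 0", path))
  bad <- setdiff(unique(df$stage), stage_codes())
  if (length(bad) > 0)
    stop(sprintf("%s: unknown stage label '%s'; allowed: %s", path, bad[1],
                 paste(stage_codes(), collapse = ", ")))
  probs <- NULL
  pcols <- paste0("p_", stage_codes())
  if (all(pcols %in% names(df))) {
    probs <- as.matrix(df[pcols])
    colnames(probs) <- stage_codes()
  }
  out <- stage_sequence(df$stage)
  out$probs <- probs
  out
}

#' @rdname read_hypnogram
#' @param stages A [stage_sequence()] to write.
#' @param seed Optional root seed recorded in the file header.
#' @export
write_hypnogram <- function(stages, path, seed = NULL) {
  stopifnot(inherits(stages, "stage_sequence"))
  df <- data.frame(epoch_index = seq_along(stages$labels) - 1L,
                   stage = stages$labels)
  if (!is.null(stages$probs))
    for (cl in colnames(stages$probs))
      df[[paste0("p_", cl)]] <- stages$probs[, cl]
  write_columns(df, path, meta = c(pipeline_version(),
                                   if (!is.null(seed)) paste("seed", seed)))
}

#' Read and write beat files
#'
#' Columns `t_s`, `ibi_s` and optionally `quality`.
#'
#' @param path File path.
#' @return `read_beats()` returns a [beat_series()].
#' @export
read_beats <- function(path) {
  df <- read_columns(path, c("t_s", "ibi_s"))
  q <- if ("quality" %in% names(df)) df$quality else NULL
  beat_series(df$t_s, df$ibi_s, q)
}

#' @rdname read_beats
#' @param beats A [beat_series()] to write.
#' @param seed Optional root seed recorded in the file header.
#' @export
write_beats <- function(beats, path, seed = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  write_columns(data.frame(t_s = beats$t, ibi_s = beats$ibi,
                           quality = beats$quality),
                path, meta = c(pipeline_version(),
                               if (!is.null(seed)) paste("seed", seed)))
}

#' Read and write 10 Hz bundle files
#'
#' Columns `t_s, ihr_bpm, ihr_valid, res, act, resact` (plus `res_valid`).
#'
#' @param path File path.
#' @return `read_bundle()` returns an [effort_bundle()].
#' @export
read_bundle <- function(path) {
  df <- read_columns(path, c("t_s", "ihr_bpm", "ihr_valid", "res", "act",
                             "resact"))
  t0 <- if (nrow(df) > 0) df$t_s[1] else 0
  rv <- if ("res_valid" %in% names(df)) as.logical(df$res_valid)
  else rep(TRUE, nrow(df))
  act1 <- df$act[seq(1, nrow(df), by = 10)]
  effort_bundle(
    ihr = gapped_series(df$ihr_bpm, 10, valid = as.logical(df$ihr_valid),
                        t0 = t0),
    res = gapped_series(df$res, 10, valid = rv, t0 = t0),
    act = df$act, act1hz = act1,
    resact = gapped_series(df$resact, 10, valid = rv, t0 = t0))
}

#' @rdname read_bundle
#' @param bundle An [effort_bundle()] to write.
#' @param seed Optional root seed recorded in the file header.
#' @export
write_bundle <- function(bundle, path, seed = NULL) {
  stopifnot(inherits(bundle, "effort_bundle"))
  write_columns(
    data.frame(t_s = series_times(bundle$ihr),
               ihr_bpm = ifelse(bundle$ihr$valid, bundle$ihr$values, NA),
               ihr_valid = as.integer(bundle$ihr$valid),
               res = bundle$res$values, res_valid = as.integer(bundle$res$valid),
               act = bundle$act, resact = bundle$resact$values),
    path, meta = c(pipeline_version(),
                   if (!is.null(seed)) paste("seed", seed)))
}

#' Serialize a stager model to a key-value text file
#'
#' @param model A `stager_model`.
#' @param path File path.
#' @return `read_stager()` returns the `stager_model`.
#' @export
write_stager <- function(model, path) {
  stopifnot(inherits(model, "stager_model"))
  obj <- list(version = pipeline_version(),
              feature_names = model$feature_names,
              coef = apply(unname(model$coef), 1, as.numeric, simplify = FALSE),
              center = as.numeric(model$center),
              scale = as.numeric(model$scale),
              transition = apply(unname(model$transition), 1, as.numeric,
                                 simplify = FALSE),
              initial = as.numeric(model$initial),
              meta = model$meta)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_stager
#' @export
read_stager <- function(path) {
  obj <- yaml::read_yaml(path)
  codes <- stage_codes()
  coef <- do.call(rbind, lapply(obj$coef, as.numeric))
  rownames(coef) <- codes
  colnames(coef) <- c("(Intercept)", obj$feature_names)
  trans <- do.call(rbind, lapply(obj$transition, as.numeric))
  dimnames(trans) <- list(codes, codes)
  structure(list(coef = coef,
                 center = stats::setNames(as.numeric(obj$center),
                                          obj$feature_names),
                 scale = stats::setNames(as.numeric(obj$scale),
                                         obj$feature_names),
                 transition = trans,
                 initial = stats::setNames(as.numeric(obj$initial), codes),
                 feature_names = obj$feature_names, meta = obj$meta),
            class = "stager_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
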