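# Plain-text interchange formats: CSV with `#`-prefixed metadata header
# lines for traces, ACF curves, fit tables and positions; 16-bit grayscale
# TIFF for images. Every writer's output round-trips through its reader.

write_meta_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (!is.null(v) && !all(is.na(v)))
      writeLines(sprintf("# %s=%s", k, paste(format(v, digits = 17),
                                             collapse = ",")), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.csv(text = lines[!is_meta])
  list(data = df, meta = meta)
}

#' Read and write photon-count trace CSV
#'
#' Columns `time_s,counts` with optional `#`-prefixed metadata lines.
#'
#' @param trace An [intensity_trace()].
#' @param path File path.
#' @param meta Extra metadata (named list) written as `# key=value` lines.
#' @return `read_trace_csv()` returns an [intensity_trace()].
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  write_meta_csv(
    data.frame(time_s = trace$dt * (seq_len(n) - 1L), counts = trace$counts),
    path, c(list(dt_s = trace$dt), trace$metadata, meta))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  x <- read_meta_csv(path)
  if (!all(c("time_s", "counts") %in% names(x$data)))
    stop("trace CSV must have columns time_s,counts")
  dt <- if (!is.null(x$meta$dt_s)) as.numeric(x$meta$dt_s)
  else stats::median(diff(x$data$time_s))
  intensity_trace(x$data$counts, dt, metadata = x$meta)
}

#' Read and write ACF curve CSV
#'
#' Columns `lag_s,G` (and `se` when present), with metadata lines
#' `# sample_id=...`, `# condition=...`, `# acquisition_time_s=...`.
#'
#' @param curve An [acf_curve()].
#' @param path File path.
#' @param meta Extra metadata (named list).
#' @return `read_acf_csv()` returns an [acf_curve()].
#' @export
write_acf_csv <- function(curve, path, meta = list()) {
  stopifnot(inherits(curve, "acf_curve"))
  df <- data.frame(lag_s = curve$lags, G = curve$values)
  if (!is.null(curve$se)) df$se <- curve$se
  write_meta_csv(df, path,
                 c(list(sample_id = curve$sample_id,
                        condition = curve$condition,
                        acquisition_time_s = curve$acquisition_time), meta))
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
read_acf_csv <- function(path) {
  x <- read_meta_csv(path)
  if (!all(c("lag_s", "G") %in% names(x$data)))
    stop("ACF CSV must have columns lag_s,G")
  acf_curve(x$data$lag_s, x$data$G, se = x$data$se,
            acquisition_time =
              if (!is.null(x$meta$acquisition_time_s))
                as.numeric(x$meta$acquisition_time_s) else NA_real_,
            sample_id = x$meta$sample_id %||% NA_character_,
            condition = x$meta$condition %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write spot-position CSV
#'
#' Columns `x_um,y_um`, with the image area recorded as metadata.
#'
#' @param positions A data.frame with `x_um`, `y_um`.
#' @param path File path.
#' @param area_um2 Image area, um^2.
#' @param meta Extra metadata.
#' @return `read_positions_csv()` returns a list `positions`, `area_um2`,
#'   `meta`.
#' @export
write_positions_csv <- function(positions, path, area_um2 = NA_real_,
                                meta = list()) {
  write_meta_csv(positions[, c("x_um", "y_um"), drop = FALSE], path,
                 c(list(area_um2 = area_um2), meta))
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  x <- read_meta_csv(path)
  list(positions = x$data,
       area_um2 = if (!is.null(x$meta$area_um2))
         as.numeric(x$meta$area_um2) else NA_real_,
       meta = x$meta)
}

#' Read and write 16-bit grayscale TIFF images
#'
#' Counts are stored as 16-bit unsigned integers (values clipped to
#' [0, 65535]); the reader returns the counts matrix.
#'
#' @param image Numeric matrix of counts.
#' @param path File path.
#' @return `read_sted_tiff()` returns a numeric matrix of counts.
#' @export
write_sted_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  scaled <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_sted_tiff
#' @export
read_sted_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 65535)
}

#' Per-curve fit table
#'
#' @param fits A list of `fcs_fit` objects.
#' @param curve_ids Optional character ids (default fit index).
#' @return A data.frame with columns `curve_id`, `model`, `N1`, `N2`,
#'   `tauD1_s`, `tauD2_s`, `D_free_um2s`, `D_bound_um2s`, `pct_bound`,
#'   `rss`, `converged`, `flags`.
#' @export
fit_table <- function(fits, curve_ids = NULL) {
  if (inherits(fits, "fcs_fit")) fits <- list(fits)
  if (is.null(curve_ids)) curve_ids <- sprintf("curve-%03d", seq_along(fits))
  do.call(rbind, Map(function(f, id) {
    one <- f$model == "one"
    data.frame(
      curve_id = id, model = f$model,
      N1 = if (one) f$params[["N"]] else f$params[["N1"]],
      N2 = if (one) NA_real_ else f$params[["N2"]],
      tauD1_s = if (one) f$params[["tau_D"]] else f$params[["tau_D1"]],
      tauD2_s = if (one) NA_real_ else f$params[["tau_D2"]],
      D_free_um2s = f$D_free, D_bound_um2s = f$D_bound,
      pct_bound = 100 * f$bound_fraction, rss = f$rss,
      converged = f$converged,
      flags = paste(f$flags, collapse = ";"))
  }, fits, curve_ids))
}
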