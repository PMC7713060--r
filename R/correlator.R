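# Software correlator: estimates the normalized fluctuation autocorrelation
# g(tau) = <dF(t) dF(t+tau)> / <F>^2 from a photon-count trace, either on a
# linear lag grid (brute force, the oracle) or on the quasi-logarithmic
# multi-tau grid of hardware correlators.

#' Photon-count intensity trace
#'
#' A uniformly sampled photon-count time series from one FCS acquisition,
#' real or simulated.
#'
#' @param counts Non-negative photon counts per sampling interval.
#' @param dt Sampling interval, s (> 0).
#' @param metadata Optional named list of free-text provenance.
#' @return An object of class `intensity_trace` with fields `dt`, `counts`,
#'   `duration` (= dt * length) and `metadata`.
#' @export
intensity_trace <- function(counts, dt, metadata = list()) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (s)")
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and >= 0")
  structure(list(dt = dt, counts = counts, duration = dt * length(counts),
                 metadata = metadata),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "Intensity trace: %d samples, dt = %g s, duration = %g s, mean = %.3g counts\n",
    length(x$counts), x$dt, x$duration, mean(x$counts)))
  invisible(x)
}

#' Autocorrelation curve
#'
#' An autocorrelation estimate G(tau) on an increasing lag grid, with
#' optional per-lag standard errors and acquisition metadata.
#'
#' @param lags Strictly increasing lag times, s.
#' @param values Correlation estimates at `lags`.
#' @param se Optional standard errors, same length as `lags`.
#' @param acquisition_time Acquisition duration, s (NA if unknown).
#' @param sample_id,condition Optional labels.
#' @return An object of class `acf_curve`.
#' @export
acf_curve <- function(lags, values, se = NULL, acquisition_time = NA_real_,
                      sample_id = NA_character_, condition = NA_character_) {
  lags <- as.numeric(lags); values <- as.numeric(values)
  if (length(lags) != length(values))
    stop("`lags` and `values` must have the same length")
  if (any(!is.finite(lags)) || any(diff(lags) <= 0) || any(lags <= 0))
    stop("`lags` must be positive and strictly increasing")
  if (any(!is.finite(values))) stop("`values` must be finite")
  if (!is.null(se)) {
    se <- as.numeric(se)
    if (length(se) != length(lags)) stop("`se` length mismatch")
  }
  structure(list(lags = lags, values = values, se = se,
                 acquisition_time = acquisition_time,
                 sample_id = sample_id, condition = condition),
            class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf(
    "ACF curve: %d lags in [%.3g, %.3g] s, G(first lag) = %.4g%s\n",
    length(x$lags), min(x$lags), max(x$lags), x$values[1L],
    if (is.na(x$sample_id)) "" else paste0(", sample ", x$sample_id)))
  invisible(x)
}

# Symmetrically normalized lag-k estimate on a count vector:
# direct and delayed running means suppress drift bias at long lags.
g_at_lag <- function(counts, k) {
  n <- length(counts)
  a <- counts[seq_len(n - k)]
  b <- counts[seq.int(k + 1L, n)]
  ma <- mean(a); mb <- mean(b)
  if (ma == 0 || mb == 0)
    stop("trace mean is zero over the correlation window; cannot normalize")
  mean(a * b) / (ma * mb) - 1
}

#' Brute-force linear-lag autocorrelation (oracle estimator)
#'
#' Computes g(tau) at every multiple of the sampling interval up to
#' `max_lag`, with symmetric normalization (the product of the running means
#' of the direct and delayed samples). Quadratic cost; intended as the
#' ground-truth oracle for [autocorrelate_multitau()] on short traces.
#'
#' @param trace An [intensity_trace()].
#' @param max_lag Largest lag, s. Default `duration / 10`; must be below
#'   `duration / 2`.
#' @return An [acf_curve()] on the linear grid dt, 2 dt, ....
#' @export
autocorrelate_linear <- function(trace, max_lag = trace$duration / 10) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  if (n < 2L) stop("trace must contain at least 2 samples")
  if (max_lag >= trace$duration / 2)
    stop("`max_lag` must be below half the trace duration")
  kmax <- max(1L, floor(max_lag / trace$dt))
  vals <- vapply(seq_len(kmax), function(k) g_at_lag(trace$counts, k),
                 numeric(1))
  acf_curve(trace$dt * seq_len(kmax), vals,
            acquisition_time = trace$duration)
}

# One multi-tau pass: returns list(lags, values) given counts and dt.
multitau_pass <- function(counts, dt, m, max_lag) {
  lags <- numeric(0); vals <- numeric(0)
  level <- 0L
  repeat {
    n <- length(counts)
    ks <- if (level == 0L) seq_len(m) else seq.int(m %/% 2L + 1L, m)
    ks <- ks[ks < n & ks * dt <= max_lag]
    if (length(ks) == 0L) break
    vals <- c(vals, vapply(ks, function(k) g_at_lag(counts, k), numeric(1)))
    lags <- c(lags, ks * dt)
    if (max(ks) * dt >= max_lag) break
    n2 <- 2L * (n %/% 2L)
    if (n2 < 2L * m + 2L) break
    counts <- counts[seq.int(1L, n2, by = 2L)] + counts[seq.int(2L, n2, by = 2L)]
    dt <- 2 * dt
    level <- level + 1L
  }
  list(lags = lags, values = vals)
}

#' Multi-tau autocorrelation on a quasi-logarithmic lag grid
#'
#' Emulates a hardware multi-tau correlator: the first block holds
#' `channels_per_block` unbinned lags at the raw sampling interval; each
#' subsequent block doubles the bin width by pairwise summation of counts
#' and contributes `channels_per_block / 2` further lags. First-block values
#' are computed identically to [autocorrelate_linear()], so the two agree
#' exactly there; at coarser levels the pre-binning acts as triangular
#' averaging of the underlying correlation.
#'
#' @param trace An [intensity_trace()].
#' @param channels_per_block Channels per resolution block (even, >= 8).
#' @param max_lag Largest lag, s. Default `duration / 10` (estimator variance
#'   grows rapidly beyond that).
#' @param n_segments If > 0, the trace is split into this many contiguous
#'   segments and per-lag standard errors are taken across segment
#'   estimates (block averaging). Default 0 (no errors).
#' @return An [acf_curve()].
#' @export
autocorrelate_multitau <- function(trace, channels_per_block = 16L,
                                   max_lag = trace$duration / 10,
                                   n_segments = 0L) {
  stopifnot(inherits(trace, "intensity_trace"))
  m <- as.integer(channels_per_block)
  if (m < 8L || m %% 2L != 0L)
    stop("`channels_per_block` must be an even integer >= 8")
  if (length(trace$counts) < 2L) stop("trace must contain at least 2 samples")
  if (max_lag >= trace$duration / 2)
    stop("`max_lag` must be below half the trace duration")
  est <- multitau_pass(trace$counts, trace$dt, m, max_lag)
  se <- NULL
  if (n_segments > 1L) {
    idx <- cut(seq_along(trace$counts), n_segments, labels = FALSE)
    seg <- lapply(split(trace$counts, idx), function(cc) {
      p <- multitau_pass(cc, trace$dt, m, max_lag)
      p$values[match(est$lags, p$lags)]
    })
    segm <- do.call(cbind, seg)
    nobs <- rowSums(!is.na(segm))
    se <- apply(segm, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(nobs, 1L))
    se[nobs < 2L] <- NA_real_
  }
  acf_curve(est$lags, est$values, se = se,
            acquisition_time = trace$duration)
}
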