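# Levenberg-Marquardt fitting of ACF curves with the one- and two-component
# diffusion models, observation-volume calibration against a reference dye,
# aggregate-spike exclusion, and per-condition batch summaries.
#
# Initialization strategy: LM is local and the two-component objective has
# local minima, so fits start from a coarse log-spaced grid of diffusion
# times (amplitudes solved linearly at each grid point, since the model is
# linear in the per-species amplitudes given the taus); the best few grid
# starts are polished with minpack.lm and the lowest residual wins.

FIT_N_BOUNDS <- c(1e-3, 1e4)

fit_weights <- function(curve, weights) {
  if (is.null(weights)) return(rep(1, length(curve$lags)))
  if (identical(weights, "relative")) {
    # matched to the multiplicative character of ACF estimator noise:
    # minimizes relative residuals, which keeps the weakly-separated
    # two-component problem well conditioned across lag decades
    w <- 1 / abs(curve$values)
    w[!is.finite(w) | curve$values <= 0] <- 0
    return(w)
  }
  if (identical(weights, "se")) {
    if (is.null(curve$se)) stop("curve carries no standard errors")
    w <- 1 / curve$se
    w[!is.finite(w)] <- 0
    return(w)
  }
  stopifnot(length(weights) == length(curve$lags))
  weights
}

# Coarse grid of candidate diffusion times: `per_decade` points per decade
# across the lag range.
tau_start_grid <- function(lags, per_decade = 3) {
  10^seq(log10(min(lags)), log10(max(lags)), by = 1 / per_decade)
}

new_fit_result <- function(model, params, se, rss, converged, flags, vol,
                           n_points) {
  w0 <- vol$w0
  if (model == "one") {
    D <- diffusion_coefficient(params[["tau_D"]], w0)
    res <- list(model = model, params = params, se = se, rss = rss,
                converged = converged, flags = flags, vol = vol,
                n_points = n_points, D_free = D, D_bound = NA_real_,
                bound_fraction = NA_real_)
  } else {
    res <- list(model = model, params = params, se = se, rss = rss,
                converged = converged, flags = flags, vol = vol,
                n_points = n_points,
                D_free = diffusion_coefficient(params[["tau_D1"]], w0),
                D_bound = diffusion_coefficient(params[["tau_D2"]], w0),
                bound_fraction =
                  params[["N2"]] / (params[["N1"]] + params[["N2"]]))
  }
  structure(res, class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("%s-component FCS fit (%s)\n",
              x$model, if (x$converged) "converged" else "NOT converged"))
  if (x$model == "one") {
    cat(sprintf("  N = %.4g, tau_D = %.4g s -> D = %.4g um^2/s\n",
                x$params[["N"]], x$params[["tau_D"]], x$D_free))
  } else {
    cat(sprintf("  N1 = %.4g, N2 = %.4g, tau_D1 = %.4g s, tau_D2 = %.4g s\n",
                x$params[["N1"]], x$params[["N2"]], x$params[["tau_D1"]],
                x$params[["tau_D2"]]))
    cat(sprintf("  D_free = %.4g, D_bound = %.4g um^2/s, bound fraction = %.3f\n",
                x$D_free, x$D_bound, x$bound_fraction))
  }
  cat(sprintf("  RSS = %.4g over %d lags", x$rss, x$n_points))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

run_lm <- function(par0, lower, upper, resid_fn) {
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], names(par0))
  }, error = function(e) stats::setNames(rep(NA_real_, length(par0)),
                                         names(par0)))
  list(par = stats::setNames(as.numeric(fit$par), names(par0)), se = se,
       rss = fit$deviance, info = fit$info)
}

flag_bounds <- function(par, lower, upper, rel = 1e-6) {
  at <- abs(par - lower) <= rel * pmax(abs(lower), 1e-300) |
    abs(par - upper) <= rel * abs(upper)
  if (any(at)) "at_bound" else character(0)
}

check_fittable <- function(curve) {
  stopifnot(inherits(curve, "acf_curve"))
  if (length(curve$lags) < 8L)
    stop("need at least 8 lag points to fit")
  if (max(curve$lags) / min(curve$lags) < 10)
    stop("lag grid must span at least one decade")
}

#' Fit the one-component diffusion model to an ACF curve
#'
#' Least-squares fit of [acf_one_component()] by Levenberg-Marquardt with
#' multi-start initialization over a log-spaced grid of diffusion times
#' (the structure parameter `z0/w0` and `gamma` are held fixed at the
#' values in `vol`). Parameter standard errors come from the Jacobian at
#' the optimum.
#'
#' @param curve An [acf_curve()] with at least 8 lags spanning a decade.
#' @param vol An [observation_volume()].
#' @param init Optional named list `N`, `tau_D` of starting values (replaces
#'   the grid search).
#' @param bounds Optional list with `tau_D = c(lo, hi)`; defaults to the lag
#'   range. `N` is always bounded to [1e-3, 1e4].
#' @param weights `"relative"` (the default: inverse curve values,
#'   minimizing relative residuals — matched to the multiplicative noise of
#'   normalized ACF estimates and well conditioned across lag decades),
#'   NULL (unweighted), `"se"` (inverse standard errors from the curve), or
#'   a numeric vector.
#' @return An object of class `fcs_fit`; see [fit_two_component()] for the
#'   two-component variant.
#' @export
fit_one_component <- function(curve, vol = observation_volume(), init = NULL,
                              bounds = NULL, weights = "relative") {
  check_fittable(curve)
  w <- fit_weights(curve, weights)
  lags <- curve$lags; vals <- curve$values
  kappa2 <- (vol$w0 / vol$z0)^2
  tau_lim <- if (!is.null(bounds$tau_D)) bounds$tau_D else range(lags)
  resid_fn <- function(p)
    w * (acf_one_component(lags, p[["N"]], p[["tau_D"]], vol) - vals)

  starts <- if (!is.null(init)) {
    list(c(N = init$N, tau_D = init$tau_D))
  } else {
    grid <- tau_start_grid(lags)
    grid <- grid[grid >= tau_lim[1] & grid <= tau_lim[2]]
    cand <- lapply(grid, function(tau) {
      g <- acf_shape(lags, tau, kappa2)
      a <- sum(w^2 * g * vals) / sum(w^2 * g^2)      # linear amplitude
      a <- min(max(a, vol$gamma / FIT_N_BOUNDS[2]), vol$gamma / FIT_N_BOUNDS[1])
      rss <- sum((w * (a * g - vals))^2)
      list(par = c(N = vol$gamma / a, tau_D = tau), rss = rss)
    })
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "rss"))]
    lapply(utils::head(cand, 3L), `[[`, "par")
  }

  lower <- c(N = FIT_N_BOUNDS[1], tau_D = tau_lim[1])
  upper <- c(N = FIT_N_BOUNDS[2], tau_D = tau_lim[2])
  fits <- lapply(starts, function(p0)
    run_lm(pmin(pmax(p0, lower), upper), lower, upper, resid_fn))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  flags <- flag_bounds(best$par, lower, upper)
  converged <- best$info %in% 1:3
  if (!converged) flags <- c(flags, "not_converged")
  new_fit_result("one", best$par, best$se, best$rss, converged, flags, vol,
                 length(lags))
}

#' Fit the two-component diffusion model to an ACF curve
#'
#' Least-squares fit of [acf_two_component()] with multi-start
#' initialization over ordered pairs of grid diffusion times (per-species
#' amplitudes solved linearly at each pair). After convergence the
#' components are put in canonical order (species 1 = fast = free); results
#' whose diffusion times differ by less than a factor `min_separation` are
#' flagged `"unresolved"`.
#'
#' @inheritParams fit_one_component
#' @param init Optional named list `N1`, `N2`, `tau_D1`, `tau_D2`.
#' @param min_separation Minimum resolvable `tau_D2 / tau_D1` ratio
#'   (default 3).
#' @return An object of class `fcs_fit` with derived `D_free`, `D_bound`
#'   and `bound_fraction = N2 / (N1 + N2)`.
#' @export
fit_two_component <- function(curve, vol = observation_volume(), init = NULL,
                              bounds = NULL, weights = "relative",
                              min_separation = 3) {
  check_fittable(curve)
  w <- fit_weights(curve, weights)
  lags <- curve$lags; vals <- curve$values
  kappa2 <- (vol$w0 / vol$z0)^2
  tau_lim <- if (!is.null(bounds$tau_D)) bounds$tau_D else range(lags)
  resid_fn <- function(p)
    w * (acf_two_component(lags, p[["N1"]], p[["N2"]], p[["tau_D1"]],
                           p[["tau_D2"]], vol) - vals)

  amp_to_N <- function(a1, a2) {
    # G = a1 g1 + a2 g2 with a_i = gamma N_i / N^2  =>  N = gamma/(a1+a2)
    N <- vol$gamma / (a1 + a2)
    c(N1 = a1 * N^2 / vol$gamma, N2 = a2 * N^2 / vol$gamma)
  }

  starts <- if (!is.null(init)) {
    list(c(N1 = init$N1, N2 = init$N2, tau_D1 = init$tau_D1,
           tau_D2 = init$tau_D2))
  } else {
    grid <- tau_start_grid(lags, per_decade = 2)
    grid <- grid[grid >= tau_lim[1] & grid <= tau_lim[2]]
    pairs <- which(outer(grid, grid, function(a, b) b / a >= min_separation),
                   arr.ind = TRUE)
    cand <- lapply(seq_len(nrow(pairs)), function(i) {
      t1 <- grid[pairs[i, 1]]; t2 <- grid[pairs[i, 2]]
      g1 <- acf_shape(lags, t1, kappa2); g2 <- acf_shape(lags, t2, kappa2)
      X <- cbind(g1, g2) * w
      a <- tryCatch(as.numeric(qr.solve(crossprod(X), crossprod(X, vals * w))),
                    error = function(e) c(NA, NA))
      if (any(!is.finite(a))) return(NULL)
      a <- pmax(a, vol$gamma / FIT_N_BOUNDS[2]^2)   # keep amplitudes positive
      rss <- sum((w * (a[1] * g1 + a[2] * g2 - vals))^2)
      list(par = c(amp_to_N(a[1], a[2]), tau_D1 = t1, tau_D2 = t2), rss = rss)
    })
    cand <- Filter(Negate(is.null), cand)
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "rss"))]
    lapply(utils::head(cand, 3L), `[[`, "par")
  }

  lower <- c(N1 = FIT_N_BOUNDS[1], N2 = FIT_N_BOUNDS[1],
             tau_D1 = tau_lim[1], tau_D2 = tau_lim[1])
  upper <- c(N1 = FIT_N_BOUNDS[2], N2 = FIT_N_BOUNDS[2],
             tau_D1 = tau_lim[2], tau_D2 = tau_lim[2])
  fits <- lapply(starts, function(p0)
    run_lm(pmin(pmax(p0, lower), upper), lower, upper, resid_fn))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]

  par <- best$par; se <- best$se
  if (par[["tau_D1"]] > par[["tau_D2"]]) {     # canonical: species 1 fast
    par <- c(N1 = par[["N2"]], N2 = par[["N1"]],
             tau_D1 = par[["tau_D2"]], tau_D2 = par[["tau_D1"]])
    se <- c(N1 = se[["N2"]], N2 = se[["N1"]],
            tau_D1 = se[["tau_D2"]], tau_D2 = se[["tau_D1"]])
  }
  flags <- flag_bounds(par, lower, upper)
  if (par[["tau_D2"]] / par[["tau_D1"]] < min_separation)
    flags <- c(flags, "unresolved")
  converged <- best$info %in% 1:3
  if (!converged) flags <- c(flags, "not_converged")
  new_fit_result("two", par, se, best$rss, converged, flags, vol,
                 length(lags))
}

#' Calibrate the observation volume from a reference-dye measurement
#'
#' Fits the one-component model to the ACF of a dye with known diffusion
#' coefficient (e.g. Atto 488, D = 400 um^2/s at 25 C) and converts the
#' fitted diffusion time into the beam waist `w0 = sqrt(4 D_ref tau_D)`.
#' The structure parameter `z_ratio` and `gamma` are instrument settings,
#' kept as configured.
#'
#' @param curve Reference-dye [acf_curve()].
#' @param D_ref Reference diffusion coefficient, um^2/s (> 0).
#' @param z_ratio Structure parameter z0/w0 for the returned volume.
#' @param gamma Illumination factor for the returned volume.
#' @return An [observation_volume()] with the calibrated `w0`. The fit is
#'   attached as attribute `"fit"`.
#' @export
calibrate_volume <- function(curve, D_ref, z_ratio = 5, gamma = 0.35) {
  if (!is.finite(D_ref) || D_ref <= 0) stop("`D_ref` must be positive")
  provisional <- observation_volume(w0 = 0.3, z_ratio = z_ratio, gamma = gamma)
  fit <- fit_one_component(curve, provisional)
  if (!fit$converged) stop("reference-dye fit did not converge")
  w0 <- sqrt(4 * D_ref * fit$params[["tau_D"]])
  out <- observation_volume(w0 = w0, z_ratio = z_ratio, gamma = gamma)
  attr(out, "fit") <- fit
  out
}

#' Choose between the one- and two-component models for a curve
#'
#' Fits both models and keeps the two-component one only if it reduces the
#' residual sum of squares significantly under a nested-model F-test at
#' level `alpha` AND its components are resolved (diffusion-time ratio at
#' least `min_separation`) AND both components carry a non-negligible
#' number fraction (at least `min_fraction`; spurious second components on
#' single-species data typically absorb smooth noise with a fraction well
#' below any physically measured bound pool). This makes explicit the
#' observation that some species (e.g. free EGFP) are fully described by a
#' single component.
#'
#' @inheritParams fit_two_component
#' @param alpha F-test significance level (default 0.05).
#' @param min_fraction Minimum number fraction of the minor component
#'   (default 0.05; the smallest measured bound pool is about 10%).
#' @return A list: `model` ("one" or "two"), `p_value` of the F-test,
#'   `fit_one`, `fit_two`, and `fit` (the selected one).
#' @export
select_model <- function(curve, vol = observation_volume(), alpha = 0.05,
                         min_separation = 3, min_fraction = 0.05,
                         weights = "relative") {
  f1 <- fit_one_component(curve, vol, weights = weights)
  f2 <- fit_two_component(curve, vol, weights = weights,
                          min_separation = min_separation)
  n <- length(curve$lags)
  df2 <- n - 4L
  p <- if (f2$rss < f1$rss && df2 > 0) {
    Fstat <- ((f1$rss - f2$rss) / 2) / (f2$rss / df2)
    stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  } else 1
  minor <- min(f2$bound_fraction, 1 - f2$bound_fraction)
  two <- p < alpha && !("unresolved" %in% f2$flags) && f2$converged &&
    minor >= min_fraction
  model <- if (two) "two" else "one"
  list(model = model, p_value = p, fit_one = f1, fit_two = f2,
       fit = if (two) f2 else f1)
}

#' Flag traces contaminated by fluorescent aggregates
#'
#' Bright slow aggregates crossing the focus produce sustained intensity
#' spikes that distort correlation curves; such acquisitions are excluded.
#' The trace is rebinned to `bin_s` bins and excluded when the binned counts
#' exceed `median + k * MAD` for at least `min_run` consecutive bins
#' (strictly above the threshold).
#'
#' @param trace An [intensity_trace()] of at least 1 s.
#' @param bin_s Rebinning interval, s (default 0.01).
#' @param k MAD multiplier (default 10).
#' @param min_run Minimum run of consecutive above-threshold bins
#'   (default 3).
#' @return A list: `keep` (logical), `threshold` (counts/bin),
#'   `offending_bins` (indices of above-threshold bins in flagged runs),
#'   `bin_s`, `n_bins`.
#' @export
exclude_aggregate_traces <- function(trace, bin_s = 0.01, k = 10,
                                     min_run = 3L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (trace$duration < 1) stop("trace must be at least 1 s long")
  per_bin <- max(1L, round(bin_s / trace$dt))
  n_bins <- length(trace$counts) %/% per_bin
  binned <- colSums(matrix(trace$counts[seq_len(n_bins * per_bin)],
                           nrow = per_bin))
  thr <- stats::median(binned) + k * stats::mad(binned)
  above <- binned > thr
  runs <- rle(above)
  bad_run <- runs$values & runs$lengths >= min_run
  offending <- integer(0)
  if (any(bad_run)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    offending <- unlist(Map(seq.int, starts[bad_run], ends[bad_run]))
  }
  list(keep = !any(bad_run), threshold = thr, offending_bins = offending,
       bin_s = per_bin * trace$dt, n_bins = n_bins)
}

#' Per-condition batch analysis of ACF curves
#'
#' Fits every curve of every condition (one-component in `"bulk"` mode;
#' in `"on_pattern"` mode the two-component model guarded by
#' [select_model()]), then summarizes each condition as mean +/- SD of the
#' diffusion coefficients and of the bound percentage `100 p_b`.
#'
#' @param curves_by_condition Named list; each element a list of
#'   [acf_curve()] objects for one condition.
#' @param vol An [observation_volume()].
#' @param mode `"bulk"` (no vesicle pattern; single diffusing species) or
#'   `"on_pattern"` (free + vesicle-bound pools).
#' @param traces_by_condition Optional named list of [intensity_trace()]
#'   lists, parallel to the curves; traces failing
#'   [exclude_aggregate_traces()] drop the matching curve.
#' @param alpha Model-selection F-test level passed to [select_model()].
#' @return A named list of `protein_summary` objects; see
#'   [summary_table()] to flatten them.
#' @export
batch_analyze <- function(curves_by_condition, vol = observation_volume(),
                          mode = c("bulk", "on_pattern"),
                          traces_by_condition = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.list(curves_by_condition), length(curves_by_condition) > 0)
  out <- lapply(names(curves_by_condition), function(cond) {
    curves <- curves_by_condition[[cond]]
    n_excluded <- 0L
    if (!is.null(traces_by_condition[[cond]])) {
      keep <- vapply(traces_by_condition[[cond]],
                     function(tr) exclude_aggregate_traces(tr)$keep,
                     logical(1))
      n_excluded <- sum(!keep)
      curves <- curves[keep]
    }
    if (length(curves) < 3L)
      stop(sprintf("condition '%s': fewer than 3 retained curves", cond))
    fits <- lapply(curves, function(cu) {
      if (mode == "bulk") fit_one_component(cu, vol)
      else select_model(cu, vol, alpha = alpha)$fit
    })
    protein_summary(cond, fits, n_excluded, mode)
  })
  stats::setNames(out, names(curves_by_condition))
}

protein_summary <- function(condition, fits, n_excluded, mode) {
  D_free <- vapply(fits, `[[`, numeric(1), "D_free")
  D_bound <- vapply(fits, `[[`, numeric(1), "D_bound")
  p_b <- vapply(fits, `[[`, numeric(1), "bound_fraction")
  two <- !is.na(D_bound)
  msd <- function(x) if (length(x)) c(mean = mean(x), sd = stats::sd(x))
  else c(mean = NA_real_, sd = NA_real_)
  structure(list(
    condition = condition, mode = mode, fits = fits,
    n_curves = length(fits), n_excluded = n_excluded,
    n_two_component = sum(two),
    D_free = msd(D_free),
    D_bound = msd(D_bound[two]),
    pct_bound = msd(100 * p_b[two]),
    bound_fractions = p_b[two]
  ), class = "protein_summary")
}

#' @export
print.protein_summary <- function(x, ...) {
  cat(sprintf("Condition '%s' (%s): %d curves (%d excluded)\n",
              x$condition, x$mode, x$n_curves, x$n_excluded))
  if (x$mode == "bulk") {
    cat(sprintf("  D_bulk = %.3g +/- %.2g um^2/s\n",
                x$D_free[["mean"]], x$D_free[["sd"]]))
  } else {
    cat(sprintf("  D_free = %.3g +/- %.2g, D_bound = %.3g +/- %.2g um^2/s, %% bound = %.1f +/- %.1f\n",
                x$D_free[["mean"]], x$D_free[["sd"]],
                x$D_bound[["mean"]], x$D_bound[["sd"]],
                x$pct_bound[["mean"]], x$pct_bound[["sd"]]))
  }
  invisible(x)
}

#' Flatten batch summaries into a table of diffusion results
#'
#' @param summaries A (named) list of summaries from [batch_analyze()].
#' @return A data.frame with one row per condition: n, exclusions, and mean
#'   +/- SD of D_bulk or of (D_free, D_bound, % bound).
#' @export
summary_table <- function(summaries) {
  if (inherits(summaries, "protein_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    if (s$mode == "bulk")
      data.frame(condition = s$condition, mode = s$mode, n = s$n_curves,
                 n_excluded = s$n_excluded,
                 D_bulk_um2s = s$D_free[["mean"]], D_bulk_sd = s$D_free[["sd"]],
                 D_free_um2s = NA_real_, D_free_sd = NA_real_,
                 D_bound_um2s = NA_real_, D_bound_sd = NA_real_,
                 pct_bound = NA_real_, pct_bound_sd = NA_real_)
    else
      data.frame(condition = s$condition, mode = s$mode, n = s$n_curves,
                 n_excluded = s$n_excluded,
                 D_bulk_um2s = NA_real_, D_bulk_sd = NA_real_,
                 D_free_um2s = s$D_free[["mean"]], D_free_sd = s$D_free[["sd"]],
                 D_bound_um2s = s$D_bound[["mean"]],
                 D_bound_sd = s$D_bound[["sd"]],
                 pct_bound = s$pct_bound[["mean"]],
                 pct_bound_sd = s$pct_bound[["sd"]])
  }))
}
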