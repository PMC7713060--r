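# Synthetic-data generators with known ground truth: Brownian-dynamics
# photon-count traces with two-state binding kinetics, directly synthesized
# noisy ACF curves, and sparse diffraction-limited spot images.

#' Configuration for a Brownian-dynamics FCS simulation
#'
#' Particles perform independent Gaussian random walks in a periodic box
#' centred on the focus, switching between a fast free state (diffusion
#' coefficient `D_free`) and a slow vesicle-bound state (`D_bound`) as a
#' two-state Markov chain with rates `r_fb` (free to bound) and `r_bf`.
#' The emitted intensity is `background` plus a 3D-Gaussian detection
#' profile summed over particles, with Poisson photon noise.
#'
#' @param D_free,D_bound Diffusion coefficients of the two states, um^2/s.
#' @param r_fb,r_bf Switching rates, 1/s (>= 0; both 0 = single species,
#'   all particles free).
#' @param n_particles Particle count in the box.
#' @param box Box edge lengths `c(Lx, Ly, Lz)`, um; each lateral edge must be
#'   at least `6 w0` and the axial edge at least `6 z0` so that the periodic
#'   images do not reach the focus.
#' @param brightness Detected counts per particle per sample at the focus.
#' @param background Background counts per sample.
#' @param dt Sampling interval, s; the per-step RMS displacement
#'   `sqrt(2 D dt)` must stay below `w0 / 5`, and `r dt` below 0.1.
#' @param duration Trace duration, s.
#' @param vol An [observation_volume()].
#' @param poisson_noise Apply Poisson photon noise (default TRUE).
#' @param init_positions Optional n x 3 matrix of starting positions, um
#'   (focus at the origin); default uniform in the box.
#' @param seed Integer seed; all randomness in [simulate_trace()] derives
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(D_free = 50, D_bound = 2, r_fb = 0, r_bf = 0,
                       n_particles = 20L, box = c(2, 2, 10),
                       brightness = 5, background = 0.2,
                       dt = 1e-5, duration = 1,
                       vol = observation_volume(),
                       poisson_noise = TRUE, init_positions = NULL,
                       seed = 1L) {
  stopifnot(inherits(vol, "observation_volume"))
  if (D_free <= 0 || D_bound <= 0) stop("diffusion coefficients must be > 0")
  if (r_fb < 0 || r_bf < 0) stop("switching rates must be >= 0")
  if (length(box) != 3L || any(box < 6 * c(vol$w0, vol$w0, vol$z0)))
    stop("box must be at least 6 x (w0, w0, z0)")
  if (dt <= 0 || duration <= dt) stop("need 0 < dt < duration")
  if (sqrt(2 * max(D_free, D_bound) * dt) >= vol$w0 / 5)
    stop("`dt` too coarse: per-step RMS displacement exceeds w0/5")
  if (max(r_fb, r_bf) * dt > 0.1)
    stop("`dt` too coarse for the switching rates (r * dt > 0.1)")
  structure(list(D_free = D_free, D_bound = D_bound, r_fb = r_fb,
                 r_bf = r_bf, n_particles = as.integer(n_particles),
                 box = box, brightness = brightness, background = background,
                 dt = dt, duration = duration, vol = vol,
                 poisson_noise = poisson_noise,
                 init_positions = init_positions, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a photon-count trace from Brownian dynamics with binding
#'
#' Integrates the model described in [sim_config()]: per-axis displacement
#' variance `2 D(state) dt`, periodic boundary wrapping, per-step state
#' switching probabilities `r_fb dt` / `r_bf dt`, 3D-Gaussian detection
#' `brightness * exp(-2 (x^2 + y^2) / w0^2 - 2 z^2 / z0^2)`, Poisson noise.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param keep_positions Also return the per-step particle positions
#'   (steps x particles matrices per axis); memory-hungry, default FALSE.
#' @return A list: `trace` (an [intensity_trace()]), `states` (steps x
#'   particles logical matrix, TRUE = bound), `bound_fraction` (realized
#'   time-share in the bound state), `config`, and (optionally)
#'   `positions`.
#' @export
simulate_trace <- function(config, keep_positions = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nsteps <- round(config$duration / config$dt)
  np <- config$n_particles
  vol <- config$vol
  if (np == 0L) {
    lambda <- rep(config$background, nsteps)
    counts <- if (config$poisson_noise) stats::rpois(nsteps, lambda) else lambda
    return(list(trace = intensity_trace(counts, config$dt,
                                        metadata = list(seed = config$seed)),
                states = matrix(logical(0), nsteps, 0), bound_fraction = NA_real_,
                config = config))
  }
  if (nsteps * np > 2e8) stop("simulation too large; reduce duration or particles")

  # initial positions (box centred on the focus) and stationary initial state
  if (is.null(config$init_positions)) {
    pos0 <- cbind(stats::runif(np, -1, 1) * config$box[1] / 2,
                  stats::runif(np, -1, 1) * config$box[2] / 2,
                  stats::runif(np, -1, 1) * config$box[3] / 2)
  } else {
    pos0 <- config$init_positions
    stopifnot(is.matrix(pos0), nrow(pos0) == np, ncol(pos0) == 3L)
  }
  p_b <- if (config$r_fb + config$r_bf > 0)
    config$r_fb / (config$r_fb + config$r_bf) else 0

  # state paths: two-state Markov chain, vectorized over particles
  states <- matrix(FALSE, nsteps, np)
  s <- stats::runif(np) < p_b
  pf <- config$r_fb * config$dt   # P(free -> bound) per step
  pb <- config$r_bf * config$dt   # P(bound -> free) per step
  for (t in seq_len(nsteps)) {
    states[t, ] <- s
    if (pf > 0 || pb > 0) {
      u <- stats::runif(np)
      s <- ifelse(s, u >= pb, u < pf)
    }
  }

  sd_step <- sqrt(2 * ifelse(states, config$D_bound, config$D_free) * config$dt)
  wrap <- function(x, L) ((x + L / 2) %% L) - L / 2
  walk_axis <- function(x0, L) {
    steps <- matrix(stats::rnorm(nsteps * np), nsteps) * sd_step
    wrap(sweep(apply(steps, 2, cumsum), 2L, x0, "+"), L)
  }
  x <- walk_axis(pos0[, 1], config$box[1])
  y <- walk_axis(pos0[, 2], config$box[2])
  z <- walk_axis(pos0[, 3], config$box[3])

  det <- exp(-2 * (x^2 + y^2) / vol$w0^2 - 2 * z^2 / vol$z0^2)
  lambda <- config$background + config$brightness * rowSums(det)
  counts <- if (config$poisson_noise) stats::rpois(nsteps, lambda) else lambda
  out <- list(trace = intensity_trace(counts, config$dt,
                                      metadata = list(seed = config$seed)),
              states = states, bound_fraction = mean(states), config = config)
  if (keep_positions) out$positions <- list(x = x, y = y, z = z)
  out
}

#' Effective particle number of a simulation configuration
#'
#' The mean particle number `N` that makes the simulated trace's
#' autocorrelation match `acf_one_component` under the `G(0) = gamma / N`
#' amplitude convention. For the 3D-Gaussian detection profile
#' `W = exp(-2 (x^2 + y^2)/w0^2 - 2 z^2/z0^2)` the zero-lag amplitude of an
#' ideal Poisson particle field at concentration `C` is
#' `1 / (C pi^{3/2} w0^2 z0)`; with `gamma = 2^{-3/2} (~0.35)` this equals
#' `gamma / N` for `N = C (pi/2)^{3/2} w0^2 z0`, which is what this helper
#' returns (times the background amplitude-dilution factor if a nonzero
#' background is configured, since uncorrelated background light raises
#' `<F>` without adding fluctuations).
#'
#' @param config A [sim_config()].
#' @return Expected effective `N` (and implied `G(0) = gamma / N`).
#' @export
effective_particle_number <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vol <- config$vol
  conc <- config$n_particles / prod(config$box)
  N <- conc * (pi / 2)^1.5 * vol$w0^2 * vol$z0
  mean_signal <- config$brightness * conc * (pi / 2)^1.5 * vol$w0^2 * vol$z0
  dilution <- (mean_signal / (mean_signal + config$background))^2
  N / dilution
}

#' Default quasi-logarithmic lag grid for synthesized curves
#'
#' @param tau_min,tau_max Grid limits, s.
#' @param n Number of lags.
#' @return Log-spaced lag vector, s.
#' @export
default_lag_grid <- function(tau_min = 2e-6, tau_max = 1, n = 160L) {
  exp(seq(log(tau_min), log(tau_max), length.out = n))
}

#' Model parameter bundles for curve synthesis and presets
#'
#' Helpers translating diffusion coefficients and a bound fraction into the
#' `(N, tau_D)` parameterization of the ACF models, via
#' `tau_D = w0^2 / (4 D)` and number-fraction splitting `N2 = p_b N`.
#'
#' @param D,D_free,D_bound Diffusion coefficients, um^2/s.
#' @param bound_fraction Bound number fraction p_b in (0, 1).
#' @param N Total mean particle number in the volume.
#' @param vol An [observation_volume()].
#' @return A named list of model parameters (`N`, `tau_D` for one component;
#'   `N1`, `N2`, `tau_D1`, `tau_D2` for two).
#' @export
one_component_params <- function(D, N = 2, vol = observation_volume()) {
  list(N = N, tau_D = diffusion_time(D, vol$w0))
}

#' @rdname one_component_params
#' @export
two_component_params <- function(D_free, D_bound, bound_fraction, N = 2,
                                 vol = observation_volume()) {
  if (bound_fraction <= 0 || bound_fraction >= 1)
    stop("`bound_fraction` must lie in (0, 1)")
  if (D_free <= D_bound) stop("need D_free > D_bound")
  list(N1 = (1 - bound_fraction) * N, N2 = bound_fraction * N,
       tau_D1 = diffusion_time(D_free, vol$w0),
       tau_D2 = diffusion_time(D_bound, vol$w0))
}

#' Synthesize noisy ACF curves directly from the closed-form models
#'
#' Fast stand-in for simulation plus correlation: each curve is the exact
#' model evaluated on `lags`, multiplied by `(1 + eps)` where `eps` is
#' zero-mean lag-correlated Gaussian noise (stationary AR(1) across the lag
#' index, marginal SD `noise_fraction`, neighbour correlation `rho`), which
#' mimics the smooth wiggles of finite-acquisition ACF estimates. With
#' `noise_fraction = 0` the curves equal the model to machine precision, and
#' the ensemble mean is unbiased for any `noise_fraction`.
#'
#' @param params Parameter list from [one_component_params()] or
#'   [two_component_params()].
#' @param vol An [observation_volume()].
#' @param noise_fraction Relative noise amplitude (>= 0).
#' @param n_curves Number of curves.
#' @param lags Lag grid, s; default [default_lag_grid()].
#' @param acquisition_time Recorded acquisition time metadata, s.
#' @param rho Lag-neighbour noise correlation in [0, 1). Default 0.8.
#' @param condition Condition label stored on each curve.
#' @param seed Integer seed (NULL = leave RNG state alone).
#' @return A list of `n_curves` [acf_curve()] objects.
#' @export
synthesize_acf <- function(params, vol = observation_volume(),
                           noise_fraction = 0, n_curves = 1L,
                           lags = default_lag_grid(),
                           acquisition_time = 30, rho = 0.8,
                           condition = NA_character_, seed = NULL) {
  if (noise_fraction < 0) stop("`noise_fraction` must be >= 0")
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  model <- if (!is.null(params$N1))
    acf_two_component(lags, params$N1, params$N2, params$tau_D1,
                      params$tau_D2, vol)
  else
    acf_one_component(lags, params$N, params$tau_D, vol)
  lapply(seq_len(n_curves), function(i) {
    v <- model
    if (noise_fraction > 0) {
      eps <- numeric(length(lags))
      eps[1] <- stats::rnorm(1, 0, noise_fraction)
      innov_sd <- noise_fraction * sqrt(1 - rho^2)
      z <- stats::rnorm(length(lags) - 1L, 0, innov_sd)
      for (j in seq_along(z)) eps[j + 1L] <- rho * eps[j] + z[j]
      v <- model * (1 + eps)
    }
    acf_curve(lags, v, acquisition_time = acquisition_time,
              sample_id = sprintf("synth-%03d", i), condition = condition)
  })
}

#' Configuration for a synthetic spot image
#'
#' Emulates a super-resolution (STED-like) image of immobilized vesicles:
#' a hard-core point process at areal density `density`, each point rendered
#' as a 2D-Gaussian point-spread function, plus Poisson noise over a uniform
#' background.
#'
#' @param density Spots per um^2 (>= 0).
#' @param pixel_size Pixel edge, um.
#' @param image_size Image edge, pixels (square image).
#' @param psf_fwhm PSF full width at half maximum, um (>= 2 pixels).
#' @param min_separation Hard-core minimum centre distance, um (0 = Poisson
#'   process).
#' @param peak Peak counts of one spot above background.
#' @param background Background counts per pixel.
#' @param seed Integer seed.
#' @return An object of class `spot_image_config`.
#' @export
spot_image_config <- function(density = 15, pixel_size = 0.02,
                              image_size = 500L, psf_fwhm = 0.06,
                              min_separation = 0.12, peak = 150,
                              background = 5, seed = 1L) {
  if (density < 0) stop("`density` must be >= 0")
  if (psf_fwhm < 2 * pixel_size)
    stop("`psf_fwhm` must be at least 2 pixels")
  if (min_separation < 0) stop("`min_separation` must be >= 0")
  structure(list(density = density, pixel_size = pixel_size,
                 image_size = as.integer(image_size), psf_fwhm = psf_fwhm,
                 min_separation = min_separation, peak = peak,
                 background = background, seed = as.integer(seed)),
            class = "spot_image_config")
}

#' Simulate a STED-like spot image with known ground truth
#'
#' Draws a Poisson-distributed number of spot centres at the configured
#' density, places them sequentially with hard-core rejection at
#' `min_separation` (bounded retries; an infeasible packing errors out),
#' renders each as a Gaussian PSF and adds Poisson noise.
#'
#' @param config A [spot_image_config()].
#' @return A list: `image` (matrix of counts, row = y), `positions`
#'   (data.frame `x_um`, `y_um` of true centres), `field_um` (image edge,
#'   um), `config`.
#' @export
simulate_sted_image <- function(config) {
  stopifnot(inherits(config, "spot_image_config"))
  set.seed(config$seed)
  L <- config$image_size * config$pixel_size
  n <- stats::rpois(1L, config$density * L^2)
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; max_attempts <- 200L * max(n, 1L)
  while (length(xs) < n) {
    if (attempts >= max_attempts)
      stop("could not place spots at the requested density and separation ",
           "(packing infeasible)")
    cx <- stats::runif(1, 0, L); cy <- stats::runif(1, 0, L)
    attempts <- attempts + 1L
    if (config$min_separation > 0 && length(xs) > 0 &&
        min((xs - cx)^2 + (ys - cy)^2) < config$min_separation^2) next
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  img <- matrix(0, config$image_size, config$image_size)
  sigma_px <- config$psf_fwhm / 2.35482 / config$pixel_size
  r <- ceiling(4 * sigma_px)
  for (i in seq_along(xs)) {
    px <- xs[i] / config$pixel_size + 0.5   # pixel centres at (j - 0.5) * size
    py <- ys[i] / config$pixel_size + 0.5
    jx <- max(1L, floor(px - r)):min(config$image_size, ceiling(px + r))
    jy <- max(1L, floor(py - r)):min(config$image_size, ceiling(py + r))
    gx <- exp(-(jx - px)^2 / (2 * sigma_px^2))
    gy <- exp(-(jy - py)^2 / (2 * sigma_px^2))
    img[jy, jx] <- img[jy, jx] + config$peak * outer(gy, gx)
  }
  img <- img + config$background
  img[] <- stats::rpois(length(img), img)
  list(image = img,
       positions = data.frame(x_um = xs, y_um = ys),
       field_um = L, config = config)
}
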