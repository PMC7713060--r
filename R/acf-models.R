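# Closed-form FCS autocorrelation models for free 3D diffusion through a
# 3D-Gaussian confocal observation volume, and the diffusion-time <->
# diffusion-coefficient conversion. Units throughout: um, s, um^2/s.

#' Confocal observation volume geometry
#'
#' Describes the effective 3D-Gaussian detection volume of a confocal FCS
#' setup: lateral waist `w0`, axial extent `z0`, and the illumination-profile
#' factor `gamma` that relates the zero-lag amplitude to the mean particle
#' number, G(0) = gamma / N.
#'
#' @param w0 Lateral 1/e^2 beam waist, um. Typical calibrated value 0.31 um.
#' @param z_ratio Structure parameter z0/w0 (volume elongation). Default 5.
#' @param z0 Axial extent, um. Overrides `z_ratio` when given.
#' @param gamma Illumination profile factor in (0, 1]. Default 0.35, a
#'   property of the instrument model; it is never fitted.
#' @return An object of class `observation_volume` with fields `w0`, `z0`,
#'   `gamma`.
#' @examples
#' vol <- observation_volume(w0 = 0.31)
#' vol$z0 / vol$w0   # structure parameter, 5
#' @export
observation_volume <- function(w0 = 0.31, z_ratio = 5, z0 = NULL,
                               gamma = 0.35) {
  if (!is.numeric(w0) || length(w0) != 1L || !is.finite(w0) || w0 <= 0)
    stop("`w0` must be a single positive number (um)")
  if (is.null(z0)) z0 <- z_ratio * w0
  if (!is.finite(z0) || z0 < w0)
    stop("`z0` must be finite and >= w0")
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    stop("`gamma` must lie in (0, 1]")
  structure(list(w0 = w0, z0 = z0, gamma = gamma),
            class = "observation_volume")
}

#' @export
print.observation_volume <- function(x, ...) {
  cat(sprintf(
    "Observation volume: w0 = %g um, z0 = %g um (z0/w0 = %g), gamma = %g\n",
    x$w0, x$z0, x$z0 / x$w0, x$gamma))
  invisible(x)
}

# Unit-amplitude single-species correlation shape g(tau); g(0) = 1.
acf_shape <- function(tau, tau_D, kappa2) {
  x <- tau / tau_D
  1 / (1 + x) / sqrt(1 + x * kappa2)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0))
    stop("`tau` must be finite and >= 0 (seconds)")
}

#' One-component diffusion autocorrelation model
#'
#' Autocorrelation of intensity fluctuations caused by a single species
#' diffusing freely in 3D through a Gaussian observation volume:
#' \deqn{G(\tau) = \frac{\gamma}{N}\,
#'   \frac{1}{1+\tau/\tau_D}\,
#'   \frac{1}{\sqrt{1+(\tau/\tau_D)(w_0/z_0)^2}}.}
#' The zero-lag amplitude is `gamma / N`.
#'
#' @param tau Lag time(s), s; non-negative.
#' @param N Mean number of fluorescent objects in the volume (> 0).
#' @param tau_D Diffusion time, s (> 0); `tau_D = w0^2 / (4 D)`.
#' @param vol An [observation_volume()].
#' @return Correlation value(s), dimensionless.
#' @examples
#' vol <- observation_volume()
#' acf_one_component(0, N = 2, tau_D = 1e-4, vol)   # 0.35 / 2
#' @export
acf_one_component <- function(tau, N, tau_D, vol = observation_volume()) {
  check_tau(tau)
  if (!is.finite(N) || N <= 0) stop("`N` must be positive")
  if (!is.finite(tau_D) || tau_D <= 0) stop("`tau_D` must be positive")
  (vol$gamma / N) * acf_shape(tau, tau_D, (vol$w0 / vol$z0)^2)
}

#' Two-component diffusion autocorrelation model
#'
#' Number-weighted mixture of two diffusing species (a fast, free pool and a
#' slow, vesicle-bound pool) with equal molecular brightness:
#' \deqn{G_2(\tau) = \frac{\gamma}{N^2}\left(N_1 g_1(\tau) + N_2 g_2(\tau)\right),
#'   \quad N = N_1 + N_2,}
#' where \eqn{g_i} is the unit-amplitude one-component shape with diffusion
#' time \eqn{\tau_{D,i}}. The zero-lag amplitude is again `gamma / N`.
#'
#' @param tau Lag time(s), s.
#' @param N1,N2 Mean numbers of objects of each species (>= 0, N1 + N2 > 0).
#' @param tau_D1,tau_D2 Diffusion times of the two species, s (> 0).
#' @param vol An [observation_volume()].
#' @return Correlation value(s), dimensionless.
#' @export
acf_two_component <- function(tau, N1, N2, tau_D1, tau_D2,
                              vol = observation_volume()) {
  check_tau(tau)
  if (any(!is.finite(c(N1, N2))) || N1 < 0 || N2 < 0 || N1 + N2 <= 0)
    stop("need N1 >= 0, N2 >= 0 and N1 + N2 > 0")
  if (any(!is.finite(c(tau_D1, tau_D2))) || tau_D1 <= 0 || tau_D2 <= 0)
    stop("diffusion times must be positive")
  N <- N1 + N2
  kappa2 <- (vol$w0 / vol$z0)^2
  (vol$gamma / N^2) *
    (N1 * acf_shape(tau, tau_D1, kappa2) + N2 * acf_shape(tau, tau_D2, kappa2))
}

#' Convert between diffusion coefficient and diffusion time
#'
#' `tau_D = w0^2 / (4 D)`: the mean dwell time of a molecule with diffusion
#' coefficient `D` in a volume of lateral waist `w0`.
#'
#' @param D Diffusion coefficient, um^2/s (> 0).
#' @param tau_D Diffusion time, s (> 0).
#' @param w0 Lateral waist, um (> 0).
#' @return `diffusion_time()` returns tau_D in s; `diffusion_coefficient()`
#'   returns D in um^2/s.
#' @examples
#' diffusion_time(400, w0 = 0.31)        # 6.00625e-5 s
#' diffusion_coefficient(6.00625e-5, w0 = 0.31)
#' @export
diffusion_time <- function(D, w0) {
  if (any(!is.finite(D)) || any(D <= 0)) stop("`D` must be positive")
  if (!is.finite(w0) || w0 <= 0) stop("`w0` must be positive")
  w0^2 / (4 * D)
}

#' @rdname diffusion_time
#' @export
diffusion_coefficient <- function(tau_D, w0) {
  if (any(!is.finite(tau_D)) || any(tau_D <= 0))
    stop("`tau_D` must be positive")
  if (!is.finite(w0) || w0 <= 0) stop("`w0` must be positive")
  w0^2 / (4 * tau_D)
}

#' Normalize an ACF curve to unit maximum
#'
#' Divides the correlation values (and standard errors, if present) by the
#' curve maximum, as done when overlaying curves of different amplitude.
#'
#' @param curve An [acf_curve()].
#' @return The curve with `max(values) == 1`; lag grid unchanged.
#' @export
normalize_acf <- function(curve) {
  stopifnot(inherits(curve, "acf_curve"))
  v <- curve$values
  m <- max(v[is.finite(v)])
  if (!is.finite(m) || m <= 0)
    stop("curve has no finite positive value to normalize by")
  curve$values <- v / m
  if (!is.null(curve$se)) curve$se <- curve$se / m
  curve
}
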