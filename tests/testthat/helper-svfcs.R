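# Shared fixtures: the calibrated observation volume used throughout the
# published measurements, and small synthetic inputs built in code.

vol310 <- observation_volume(w0 = 0.31, z_ratio = 5, gamma = 0.35)

# A deterministic two-spot image: Gaussian peaks of the given FWHM (um)
# at positions (x_um, y_um) on a background, no noise.
render_spots <- function(positions, image_size = 64L, pixel_size = 0.02,
                         psf_fwhm = 0.06, peak = 100, background = 0) {
  img <- matrix(background, image_size, image_size)
  sigma <- psf_fwhm / 2.35482 / pixel_size
  for (i in seq_len(nrow(positions))) {
    px <- positions$x_um[i] / pixel_size + 0.5
    py <- positions$y_um[i] / pixel_size + 0.5
    gx <- exp(-(seq_len(image_size) - px)^2 / (2 * sigma^2))
    gy <- exp(-(seq_len(image_size) - py)^2 / (2 * sigma^2))
    img <- img + peak * outer(gy, gx)
  }
  img
}

mean_and_se <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
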