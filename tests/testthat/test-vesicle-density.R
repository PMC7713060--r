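# Image analysis: bandpass filtering, spot detection with subpixel
# refinement, and density / spacing statistics.

test_that("difference-of-Gaussians filter kills DC and centres an impulse", {
  const <- matrix(7, 50, 50)
  f <- bandpass_filter(const, pixel_size = 0.02)
  expect_lt(max(abs(f)), 1e-8)
  imp <- matrix(0, 51, 51); imp[26, 26] <- 1
  fi <- bandpass_filter(imp, pixel_size = 0.02)
  expect_equal(which(fi == max(fi), arr.ind = TRUE)[1, ],
               c(row = 26, col = 26))
  # radial symmetry of the kernel imprint
  expect_equal(fi[26, 21], fi[26, 31], tolerance = 1e-10)
  expect_equal(fi[21, 26], fi[31, 26], tolerance = 1e-10)
  expect_error(bandpass_filter(array(0, c(4, 4, 2)), 0.02), "matrix")
  expect_error(bandpass_filter(const, 0.02, sigma_small = 0.1,
                               sigma_large = 0.05), "sigma_small")
})

test_that("high-frequency structure is attenuated per the Gaussian response", {
  # alternating columns: a Nyquist (period 2 px) grating, far above the
  # small-sigma cutoff; the Gaussian MTF there is exp(-2 pi^2 sigma^2 f^2)
  # ~ 7e-3 for sigma = 1 px, f = 0.5 cyc/px
  n <- 64
  s <- outer(rep(1, n), cos(pi * seq_len(n)))
  f <- bandpass_filter(s, pixel_size = 0.02, sigma_small = 0.02,
                       sigma_large = 0.12)
  inner <- 10:54
  atten <- max(abs(f[inner, inner])) / max(abs(s))
  expect_lt(atten, 0.05)
})

test_that("well-separated spots are recovered within a pixel", {
  cfg <- spot_image_config(density = 1, image_size = 500L, pixel_size = 0.02,
                           psf_fwhm = 0.06, min_separation = 0.3,
                           peak = 150, background = 5, seed = 41)
  sim <- simulate_sted_image(cfg)    # ~100 spots at high SNR
  filt <- bandpass_filter(sim$image, cfg$pixel_size, psf_fwhm = cfg$psf_fwhm)
  spots <- detect_spots(filt, cfg$pixel_size)
  truth <- sim$positions
  d <- as.matrix(dist(rbind(as.matrix(truth),
                            as.matrix(spots$positions))))
  cross <- d[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(spots$positions)),
             drop = FALSE]
  hits <- sum(apply(cross, 1L, min) <= cfg$pixel_size)
  expect_gte(hits / nrow(truth), 0.95)
  expect_lte(abs(nrow(spots$positions) - nrow(truth)), 0.05 * nrow(truth))
})

test_that("a blank noisy field yields almost no detections at k = 5", {
  cfg <- spot_image_config(density = 0, image_size = 500L, background = 5,
                           seed = 3)
  sim <- simulate_sted_image(cfg)
  filt <- bandpass_filter(sim$image, cfg$pixel_size, psf_fwhm = cfg$psf_fwhm)
  spots <- detect_spots(filt, cfg$pixel_size)
  expect_lte(nrow(spots$positions), 10)   # out of 2.5e5 pixels
})

test_that("spots closer than the suppression radius merge into one", {
  pos <- data.frame(x_um = c(0.60, 0.64), y_um = c(0.64, 0.64))
  img <- render_spots(pos, image_size = 64L, peak = 100) +
    matrix(1, 64, 64)
  filt <- bandpass_filter(img, 0.02)
  spots <- detect_spots(filt, 0.02, k = 5, min_distance = 0.1)
  expect_equal(nrow(spots$positions), 1L)
})

test_that("detection is translation invariant to subpixel tolerance", {
  pos <- data.frame(x_um = c(0.31, 0.83), y_um = c(0.41, 0.91))
  img1 <- render_spots(pos, image_size = 80L, background = 2)
  shift <- 0.06   # 3 pixels
  img2 <- render_spots(transform(pos, x_um = x_um + shift), image_size = 80L,
                       background = 2)
  s1 <- detect_spots(bandpass_filter(img1, 0.02), 0.02)
  s2 <- detect_spots(bandpass_filter(img2, 0.02), 0.02)
  o1 <- s1$positions[order(s1$positions$x_um), ]
  o2 <- s2$positions[order(s2$positions$x_um), ]
  expect_equal(o2$x_um - o1$x_um, rep(shift, 2), tolerance = 0.02)
  expect_equal(o2$y_um, o1$y_um, tolerance = 0.01)
})

test_that("density and spacing follow from geometry", {
  # 4x4 grid, 0.25 um pitch, 1 um^2 field
  g <- expand.grid(x_um = (0:3) * 0.25, y_um = (0:3) * 0.25)
  ds <- density_and_spacing(g, area_um2 = 1)
  expect_equal(ds$density_um2, 16)
  expect_equal(ds$nn_distance_nm, 250)
  # single spot: density defined, spacing missing
  one <- density_and_spacing(data.frame(x_um = 0.5, y_um = 0.5),
                             area_um2 = 4)
  expect_equal(one$density_um2, 0.25)
  expect_true(is.na(one$nn_distance_nm))
})
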