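# Synthetic generators: Brownian dynamics with two-state binding, direct
# ACF synthesis, and spot images — each validated against closed-form
# ground truth.

test_that("trace simulation handles the degenerate configurations", {
  # zero particles: Poisson noise around the background
  cfg <- sim_config(D_free = 1, D_bound = 1, n_particles = 0,
                    background = 4, duration = 0.2,
                    dt = 1e-4, vol = vol310, seed = 5)
  sim <- simulate_trace(cfg)
  expect_equal(mean(sim$trace$counts), 4, tolerance = 0.1)
  expect_true(is.na(sim$bound_fraction))
  # one immobile particle at the focus, no noise: constant intensity
  cfg <- sim_config(D_free = 1e-9, D_bound = 1e-9, n_particles = 1,
                    brightness = 7, background = 0.5, duration = 0.05,
                    dt = 1e-4, vol = vol310, poisson_noise = FALSE,
                    init_positions = matrix(0, 1, 3), seed = 1)
  sim <- simulate_trace(cfg)
  expect_equal(sim$trace$counts, rep(7.5, 500), tolerance = 1e-6)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(dt = 1e-3, D_free = 85, vol = vol310), "RMS")
  expect_error(sim_config(r_fb = 200, r_bf = 200, dt = 1e-3,
                          D_free = 1, D_bound = 1, vol = vol310),
               "switching rates")
  expect_error(sim_config(box = c(1, 1, 5), vol = vol310), "6 x")
})

test_that("two-state switching reaches the Markov stationary occupancy", {
  cfg <- sim_config(D_free = 1, D_bound = 1, r_fb = 30, r_bf = 70,
                    n_particles = 50, dt = 1e-3, duration = 2,
                    vol = vol310, seed = 8)
  sim <- simulate_trace(cfg)
  # stationary bound fraction r_fb / (r_fb + r_bf) = 0.3
  expect_equal(sim$bound_fraction, 0.3, tolerance = 0.1)
  expect_lt(abs(sim$bound_fraction - 0.3), 0.03)   # ~5 binomial SE
})

test_that("free-particle displacements obey the MSD law", {
  cfg <- sim_config(D_free = 5, D_bound = 5, n_particles = 100,
                    dt = 1e-4, duration = 0.2, vol = vol310, seed = 13)
  sim <- simulate_trace(cfg, keep_positions = TRUE)
  L <- cfg$box[1]
  for (k in c(1L, 5L, 20L)) {
    x <- sim$positions$x
    d <- x[-seq_len(k), ] - x[seq_len(nrow(x) - k), ]
    d <- ((d + L / 2) %% L) - L / 2          # minimum-image displacement
    expect_equal(mean(d^2), 2 * 5 * k * 1e-4, tolerance = 0.1)
  }
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(D_free = 5, D_bound = 5, n_particles = 10,
                    duration = 0.05, dt = 1e-4, vol = vol310, seed = 99)
  expect_identical(simulate_trace(cfg)$trace$counts,
                   simulate_trace(cfg)$trace$counts)
  cfg2 <- sim_config(D_free = 5, D_bound = 5, n_particles = 10,
                     duration = 0.05, dt = 1e-4, vol = vol310, seed = 100)
  expect_false(identical(simulate_trace(cfg)$trace$counts,
                         simulate_trace(cfg2)$trace$counts))
})

test_that("noiseless synthesized curves equal the closed-form model", {
  p1 <- one_component_params(85, N = 2, vol = vol310)
  cu <- synthesize_acf(p1, vol310, noise_fraction = 0)[[1]]
  expect_equal(cu$values,
               acf_one_component(cu$lags, 2, p1$tau_D, vol310))
  p2 <- two_component_params(67, 4, 0.15, N = 2, vol = vol310)
  cu2 <- synthesize_acf(p2, vol310, noise_fraction = 0)[[1]]
  expect_equal(cu2$values,
               acf_two_component(cu2$lags, p2$N1, p2$N2, p2$tau_D1,
                                 p2$tau_D2, vol310))
})

test_that("synthesized noise is unbiased and seed-deterministic", {
  p <- one_component_params(85, N = 2, vol = vol310)
  curves <- synthesize_acf(p, vol310, noise_fraction = 0.05,
                           n_curves = 500, seed = 4)
  model <- acf_one_component(curves[[1]]$lags, 2, p$tau_D, vol310)
  i <- 20   # a lag in the decaying region
  vals <- vapply(curves, function(cu) cu$values[i], numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - model[i]) / se, 3)
  again <- synthesize_acf(p, vol310, noise_fraction = 0.05,
                          n_curves = 2, seed = 4)
  expect_identical(again[[1]]$values, curves[[1]]$values)
  other <- synthesize_acf(p, vol310, noise_fraction = 0.05,
                          n_curves = 1, seed = 5)
  expect_false(identical(other[[1]]$values, curves[[1]]$values))
})

test_that("spot images honour density, hard core and ground truth", {
  # density 0: pure noise, empty ground truth
  cfg0 <- spot_image_config(density = 0, image_size = 100L, seed = 2)
  sim0 <- simulate_sted_image(cfg0)
  expect_equal(nrow(sim0$positions), 0)
  expect_equal(mean(sim0$image), cfg0$background, tolerance = 0.2)
  # density 15 on a 10x10 um field: ~1500 spots (Poisson)
  cfg <- spot_image_config(density = 15, image_size = 500L,
                           pixel_size = 0.02, seed = 7)
  sim <- simulate_sted_image(cfg)
  expect_gt(nrow(sim$positions), 1500 - 4 * sqrt(1500))
  expect_lt(nrow(sim$positions), 1500 + 4 * sqrt(1500))
  # hard core respected
  d <- as.matrix(dist(sim$positions)); diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation)
  # infeasible packing errors out
  expect_error(simulate_sted_image(
    spot_image_config(density = 15, min_separation = 0.4, image_size = 200L,
                      seed = 1)), "packing")
})

test_that("a pure Poisson point pattern has the closed-form NN spacing", {
  cfg <- spot_image_config(density = 15, min_separation = 0, image_size = 500L,
                           pixel_size = 0.02, seed = 9)
  sim <- simulate_sted_image(cfg)
  ds <- density_and_spacing(sim$positions, area_um2 = sim$field_um^2)
  expect_equal(ds$nn_distance_nm, 1000 / (2 * sqrt(15)), tolerance = 0.06)
})
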