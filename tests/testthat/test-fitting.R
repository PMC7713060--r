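# Curve fitting: self-consistency on exact model data, calibration,
# model selection, aggregate exclusion, and batch summaries.

test_that("one-component fit recovers exact model data to high precision", {
  tau_D <- 6.00625e-5
  cu <- synthesize_acf(list(N = 1, tau_D = tau_D), vol310,
                       noise_fraction = 0)[[1]]
  f <- fit_one_component(cu, vol310)
  expect_true(f$converged)
  expect_lt(abs(f$params[["tau_D"]] - tau_D) / tau_D, 1e-6)
  expect_lt(abs(f$params[["N"]] - 1), 1e-6)
  expect_equal(f$D_free, 400, tolerance = 1e-6)   # w0 = 0.31 um
})

test_that("two-component fit recovers exact model data", {
  p <- two_component_params(60, 4, 0.15, N = 2, vol = vol310)  # tau ratio 15
  cu <- synthesize_acf(p, vol310, noise_fraction = 0)[[1]]
  f <- fit_two_component(cu, vol310)
  expect_true(f$converged)
  expect_false("unresolved" %in% f$flags)
  for (nm in names(p))
    expect_lt(abs(f$params[[nm]] - p[[nm]]) / p[[nm]], 1e-4)
  expect_equal(f$bound_fraction, 0.15, tolerance = 1e-4)
})

test_that("two-component fit flags a single-species curve as degenerate", {
  cu <- synthesize_acf(list(N = 2, tau_D = 3e-4), vol310,
                       noise_fraction = 0)[[1]]
  f <- fit_two_component(cu, vol310)
  degenerate <- "unresolved" %in% f$flags ||
    f$params[["N2"]] < 0.01 * f$params[["N1"]] || "at_bound" %in% f$flags
  expect_true(degenerate)
})

test_that("fits report canonical ordering: fast component first", {
  curves <- synthesize_preset("anti-goat-antibody", "on_pattern",
                              n_curves = 8, seed = 31)
  for (cu in curves) {
    f <- fit_two_component(cu, vol310)
    expect_lt(f$params[["tau_D1"]], f$params[["tau_D2"]])
    expect_gt(f$D_free, f$D_bound)
  }
})

test_that("LM polishing never worsens the starting residual", {
  curves <- synthesize_preset("alpha-Synuclein-on-SV", "on_pattern",
                              n_curves = 5, seed = 17)
  p <- two_component_params(67, 4, 0.15, N = 2, vol = vol310)
  for (cu in curves) {
    w <- 1 / abs(cu$values)
    rss0 <- sum((w * (acf_two_component(cu$lags, p$N1, p$N2, p$tau_D1,
                                        p$tau_D2, vol310) - cu$values))^2)
    f <- fit_two_component(cu, vol310, init = p)
    expect_lte(f$rss, rss0 + 1e-12)
  }
})

test_that("volume calibration inverts the diffusion-time relation", {
  cu <- synthesize_acf(list(N = 1, tau_D = 6.00625e-5), vol310,
                       noise_fraction = 0)[[1]]
  cal <- calibrate_volume(cu, D_ref = 400)
  expect_equal(cal$w0, 0.310, tolerance = 1e-6)
  expect_equal(cal$z0 / cal$w0, 5)
  # homogeneity: doubling D_ref scales w0 by sqrt(2)
  cal2 <- calibrate_volume(cu, D_ref = 800)
  expect_equal(cal2$w0 / cal$w0, sqrt(2), tolerance = 1e-6)
})

test_that("calibration round-trips a synthesized volume to <1%", {
  truth <- observation_volume(w0 = 0.27, z_ratio = 5)
  cu <- synthesize_acf(one_component_params(400, N = 1, vol = truth), truth,
                       noise_fraction = 0)[[1]]
  cal <- calibrate_volume(cu, D_ref = 400)
  expect_lt(abs(cal$w0 - 0.27) / 0.27, 0.01)
})

test_that("model selection keeps one component for single-species data", {
  cu <- synthesize_acf(list(N = 2, tau_D = 3e-4), vol310,
                       noise_fraction = 0)[[1]]
  expect_identical(select_model(cu, vol310)$model, "one")
  # noisy single-species curves select "one" in >= 95% of seeds
  curves <- synthesize_preset("EGFP", "bulk", n_curves = 20,
                              noise_fraction = 0.02, seed = 12)
  picks <- vapply(curves, function(cu) select_model(cu, vol310)$model, "")
  expect_gte(mean(picks == "one"), 0.95)
})

test_that("model selection finds two components under strong separation", {
  curves <- synthesize_preset("alpha-Synuclein-on-SV", "on_pattern",
                              n_curves = 10, seed = 14)
  picks <- vapply(curves, function(cu) select_model(cu, vol310)$model, "")
  expect_true(all(picks == "two"))
})

test_that("aggregate exclusion flags sustained spikes and keeps clean traces", {
  set.seed(6)
  clean <- intensity_trace(rpois(2e4, 20), 1e-4)   # 2 s stationary
  expect_true(exclude_aggregate_traces(clean)$keep)
  spiked <- clean
  spiked$counts[5001:6000] <- spiked$counts[5001:6000] * 50   # 100 ms burst
  res <- exclude_aggregate_traces(spiked)
  expect_false(res$keep)
  expect_gte(length(res$offending_bins), 10)
  # boundary contract: bins exactly at the threshold are kept (strict >)
  flat <- intensity_trace(rep(10, 2e4), 1e-4)      # MAD = 0, threshold = median
  expect_true(exclude_aggregate_traces(flat)$keep)
  just_above <- flat
  just_above$counts[1001:1400] <- 11               # 4 bins strictly above
  expect_false(exclude_aggregate_traces(just_above)$keep)
  expect_error(exclude_aggregate_traces(intensity_trace(rpois(100, 5), 1e-3)),
               "1 s")
})

test_that("batch analysis summarizes per condition with schema by mode", {
  curves <- list(
    egfp = synthesize_preset("EGFP", "bulk", n_curves = 5, seed = 3),
    syn = synthesize_preset("alpha-Synuclein-on-SV", "bulk", n_curves = 5,
                            seed = 4))
  sums <- batch_analyze(curves, vol310, mode = "bulk")
  tab <- summary_table(sums)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$D_bound_um2s)))        # no bound pool in bulk
  expect_true(all(is.finite(tab$D_bulk_um2s)))
  # duplicated identical curves give SD = 0
  one <- synthesize_preset("EGFP", "bulk", n_curves = 1, seed = 3)[[1]]
  dup <- batch_analyze(list(egfp = list(one, one, one)), vol310, "bulk")
  expect_equal(summary_table(dup)$D_bulk_sd, 0)
  expect_error(batch_analyze(list(egfp = list(one, one)), vol310, "bulk"),
               "fewer than 3")
})

test_that("batch exclusion drops curves whose traces carry aggregates", {
  set.seed(44)
  clean <- intensity_trace(rpois(2e4, 20), 1e-4)
  spiked <- clean
  spiked$counts[1:1000] <- spiked$counts[1:1000] * 50
  curves <- synthesize_preset("EGFP", "bulk", n_curves = 4, seed = 9)
  sums <- batch_analyze(list(egfp = curves), vol310, "bulk",
                        traces_by_condition =
                          list(egfp = list(clean, clean, clean, spiked)))
  expect_equal(sums$egfp$n_excluded, 1L)
  expect_equal(sums$egfp$n_curves, 3L)
})
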