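# End-to-end orchestration of the two measurement pipelines (bulk and
# on-pattern) plus the image-density pipeline: synthesize or load inputs,
# exclude contaminated acquisitions, fit, summarize, derive energetics and
# group statistics, and write all result tables with seed and config-hash
# metadata. Deterministic given the configured seeds.

#' Build a pipeline run configuration
#'
#' @param conditions Character vector of preset names (see [sv_presets()])
#'   analyzed in the bulk / on-pattern modes.
#' @param n_curves Curves synthesized per condition.
#' @param noise_fraction Relative ACF noise amplitude.
#' @param N Total mean particle number per curve.
#' @param w0,z_ratio,gamma Observation-volume parameters.
#' @param alpha Model-selection F-test level.
#' @param averaging Energetics averaging mode (see [energetics_table()]).
#' @param image Named list of [spot_image_config()] arguments for density
#'   mode.
#' @param detect Named list: `k`, `min_distance` for [detect_spots()].
#' @param seed Master integer seed; per-condition seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions = c("EGFP", "Synapsin-EGFP"),
                       n_curves = 25L, noise_fraction = 0.02, N = 2,
                       w0 = 0.31, z_ratio = 5, gamma = 0.35,
                       alpha = 0.05, averaging = "per_point",
                       image = list(), detect = list(),
                       seed = 1L) {
  cfg <- list(conditions = conditions, n_curves = as.integer(n_curves),
              noise_fraction = noise_fraction, N = N,
              w0 = w0, z_ratio = z_ratio, gamma = gamma, alpha = alpha,
              averaging = averaging, image = image, detect = detect,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file holds any subset of the [run_config()] arguments by name.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run a full analysis pipeline and write results to disk
#'
#' Modes:
#' \describe{
#'   \item{bulk}{Per condition: synthesize one-component curves at the
#'     preset's bulk diffusion coefficient, fit, summarize. Writes
#'     `fits_<condition>.csv` and `summary.csv`.}
#'   \item{on_pattern}{Per condition: synthesize two-component curves at
#'     the preset's free/bound values, fit with the model-selection guard,
#'     summarize, derive energetics, and compare bound-component diffusion
#'     across conditions (Kruskal-Wallis + pairwise post hoc). Writes the
#'     fit tables, `summary.csv`, `energetics.csv` and `pvalues.csv`.}
#'   \item{density}{Simulate a spot image, bandpass-filter, detect spots,
#'     and write `image.tif`, `positions_true.csv`,
#'     `positions_detected.csv` and `density.csv`.}
#' }
#' Every CSV carries `# seed=` and `# config_hash=` metadata; identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [run_config()] (or a YAML path for [read_run_config()]).
#' @param mode `"bulk"`, `"on_pattern"` or `"density"`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config, mode = c("bulk", "on_pattern", "density"),
                         out_dir = tempfile("svfcs-run-")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vol <- observation_volume(w0 = config$w0, z_ratio = config$z_ratio,
                            gamma = config$gamma)
  meta <- list(seed = config$seed, config_hash = rlang::hash(config),
               mode = mode)
  paths <- character(0)

  if (mode == "density") {
    img_cfg <- do.call(spot_image_config,
                       c(config$image, list(seed = config$seed)))
    sim <- simulate_sted_image(img_cfg)
    filt <- bandpass_filter(sim$image, img_cfg$pixel_size,
                            psf_fwhm = img_cfg$psf_fwhm)
    det_args <- c(list(filtered = filt, pixel_size = img_cfg$pixel_size),
                  config$detect)
    spots <- do.call(detect_spots, det_args)
    ds <- density_and_spacing(spots)
    p_img <- file.path(out_dir, "image.tif")
    write_sted_tiff(sim$image, p_img)
    p_true <- file.path(out_dir, "positions_true.csv")
    write_positions_csv(sim$positions, p_true, area_um2 = sim$field_um^2,
                        meta = meta)
    p_det <- file.path(out_dir, "positions_detected.csv")
    write_positions_csv(spots$positions, p_det, area_um2 = spots$area_um2,
                        meta = meta)
    p_dens <- file.path(out_dir, "density.csv")
    write_meta_csv(data.frame(n_spots = ds$n_spots,
                              density_um2 = ds$density_um2,
                              nn_distance_nm = ds$nn_distance_nm,
                              threshold = spots$threshold, k = spots$k),
                   p_dens, meta)
    return(invisible(list(simulation = sim, spots = spots, density = ds,
                          paths = c(p_img, p_true, p_det, p_dens),
                          out_dir = out_dir)))
  }

  curves <- list()
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[i]
    curves[[cond]] <- synthesize_preset(
      cond, mode = if (mode == "bulk") "bulk" else "on_pattern",
      n_curves = config$n_curves, noise_fraction = config$noise_fraction,
      N = config$N, vol = vol, seed = config$seed + i)
  }
  summaries <- batch_analyze(curves, vol, mode = mode, alpha = config$alpha)
  for (cond in names(summaries)) {
    p <- file.path(out_dir, sprintf("fits_%s.csv", gsub("[^A-Za-z0-9.-]", "_", cond)))
    write_meta_csv(fit_table(summaries[[cond]]$fits),
                   p, c(meta, list(condition = cond)))
    paths <- c(paths, p)
  }
  p_sum <- file.path(out_dir, "summary.csv")
  write_meta_csv(summary_table(summaries), p_sum, meta)
  paths <- c(paths, p_sum)
  result <- list(summaries = summaries, out_dir = out_dir)

  if (mode == "on_pattern") {
    en <- energetics_table(summaries, averaging = config$averaging)
    p_en <- file.path(out_dir, "energetics.csv")
    write_meta_csv(en, p_en, meta)
    paths <- c(paths, p_en)
    result$energetics <- en
    d_bound <- lapply(summaries, function(s)
      vapply(s$fits, `[[`, numeric(1), "D_bound"))
    d_bound <- lapply(d_bound, function(v) v[is.finite(v)])
    d_bound <- d_bound[lengths(d_bound) >= 2L]
    if (length(d_bound) >= 2L) {
      kw <- kruskal_wallis(d_bound)
      ph <- posthoc_pairwise(d_bound)
      pm <- rbind(data.frame(group1 = "all", group2 = "all",
                             statistic = kw$statistic, p_value = kw$p_value,
                             method = kw$method), ph)
      p_pv <- file.path(out_dir, "pvalues.csv")
      write_meta_csv(pm, p_pv, meta)
      paths <- c(paths, p_pv)
      result$stats <- list(kruskal_wallis = kw, posthoc = ph)
    }
  }
  result$paths <- paths
  invisible(result)
}
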