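# Simulation presets encoding the published study conditions: per-protein
# bulk and on-pattern diffusion coefficients and bound percentages for
# mEGFP-tagged synaptic proteins over a patterned synaptic-vesicle layer,
# plus the two antibody controls. Generating values are the published
# means; SDs are carried along as provenance.

#' Published study-condition presets
#'
#' One row per measured condition. `D_bulk` is the free-solution diffusion
#' coefficient; `D_free`/`D_bound` are the fast (free) and slow
#' (vesicle-bound or confined) components measured over the vesicle
#' pattern; `pct_bound` is the bound time-share in percent. For the two
#' antibody controls the published curves carry no bound percentage, so the
#' preset bound fractions there are package choices (30% for the
#' SV-interacting anti-goat antibody, 20% for the confined-only anti-rat
#' antibody); only their D values are treated as generating truths.
#'
#' @return A data.frame with columns `condition`, `kind`
#'   (protein/control), `D_bulk`, `D_bulk_sd`, `D_free`, `D_bound`,
#'   `D_bound_sd`, `pct_bound`, `pct_bound_sd`, `mw_kda`, `provenance`.
#'   Units: um^2/s and percent.
#' @examples
#' sv_presets()[sv_presets()$condition == "EGFP", ]
#' @export
sv_presets <- function() {
  p <- function(condition, D_bulk, D_bulk_sd, D_bound, D_bound_sd,
                pct_bound, pct_bound_sd, mw_kda, D_free = D_bulk,
                kind = "protein", provenance = "published per-protein diffusion summary") {
    data.frame(condition = condition, kind = kind, D_bulk = D_bulk,
               D_bulk_sd = D_bulk_sd, D_free = D_free, D_bound = D_bound,
               D_bound_sd = D_bound_sd, pct_bound = pct_bound,
               pct_bound_sd = pct_bound_sd, mw_kda = mw_kda,
               provenance = provenance)
  }
  rbind(
    p("Amphiphysin-mEGFP",   72, 31, 2.2, 2.4, 24, 13, 105),
    p("alpha-Synuclein-mEGFP", 60, 16, 1.8, 2.0, 15, 12, 44),
    p("CALM-mEGFP",          28, 13, 2.8, 2.5, 10, 10, 99),
    p("Calmodulin1-mEGFP",   79, 13, 2.3, 2.5, 10, 11, 47),
    p("Clathrin-LC-B-mEGFP", 64, 13, 3.3, 2.7, 22, 18, 55),
    p("Complexin1-mEGFP",    50, 11, 1.6, 1.6, 17, 14, 45),
    p("EGFP",                85,  6, NA,  NA,  NA, NA, 28,
      provenance = "published non-interacting control; one-component only"),
    p("EndophilinA1-mEGFP",  50, 12, 2.4, 2.3, 14, 14, 70),
    p("Epsin-mEGFP",         15, 10, 2.4, 2.7, 16, 11, 90),
    p("Rab3a-mEGFP",         55, 14, 3.2, 2.9, 15, 12, 55),
    p("Rab7a-mEGFP",         32, 23, 2.8, 3.1, 17, 14, 53),
    p("Synapsin-EGFP",       33,  3, 3.3, 2.6, 30, 18, 102),
    # On-pattern alpha-synuclein control: distinct published free/bound pair.
    p("alpha-Synuclein-on-SV", 59, 15, 4, 2, 15, 12, 44, D_free = 67,
      kind = "control",
      provenance = "published on-pattern control curve (free 67, bound 4)"),
    p("anti-goat-antibody",  55, 20, 2, 1, 30, NA, NA, D_free = 49,
      kind = "control",
      provenance = "published interacting-antibody control (free 49, bound 2); bound fraction is a package choice"),
    p("anti-rat-antibody",   47, 29, 8, 5, 20, NA, NA, D_free = 43,
      kind = "control",
      provenance = "published non-interacting-antibody control (free 43, confined 8); bound fraction is a package choice")
  )
}

#' Look up one preset row by condition name
#'
#' @param condition A `condition` value of [sv_presets()].
#' @return A one-row data.frame.
#' @export
sv_preset <- function(condition) {
  tab <- sv_presets()
  row <- tab[tab$condition == condition, ]
  if (nrow(row) != 1L)
    stop("unknown preset '", condition, "'; see sv_presets()$condition")
  row
}

#' Synthesize ACF curves for a named preset condition
#'
#' Convenience wrapper around [synthesize_acf()]: builds the model
#' parameters from the preset's generating values (one-component at
#' `D_bulk` in `"bulk"` mode; two-component at `D_free`, `D_bound`,
#' `pct_bound` in `"on_pattern"` mode) and returns the curves.
#'
#' @param condition Preset name, see [sv_presets()].
#' @param mode `"bulk"` or `"on_pattern"`.
#' @param n_curves Number of curves.
#' @param noise_fraction Relative noise amplitude (default 0.02).
#' @param N Total mean particle number in the volume.
#' @param vol An [observation_volume()].
#' @param seed Integer seed.
#' @param ... Passed on to [synthesize_acf()].
#' @return A list of [acf_curve()] objects.
#' @export
synthesize_preset <- function(condition, mode = c("bulk", "on_pattern"),
                              n_curves = 25L, noise_fraction = 0.02, N = 2,
                              vol = observation_volume(), seed = 1L, ...) {
  mode <- match.arg(mode)
  row <- sv_preset(condition)
  params <- if (mode == "bulk") {
    one_component_params(row$D_bulk, N = N, vol = vol)
  } else {
    if (!is.finite(row$D_bound))
      stop("preset '", condition, "' has no bound component")
    two_component_params(row$D_free, row$D_bound, row$pct_bound / 100,
                         N = N, vol = vol)
  }
  synthesize_acf(params, vol = vol, noise_fraction = noise_fraction,
                 n_curves = n_curves, condition = condition, seed = seed, ...)
}
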