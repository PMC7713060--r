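# Two-state Boltzmann interaction energetics: the bound fraction p_b is the
# equilibrium occupancy of a bound state b relative to a free state f, so
# p_b/p_f = exp((E_f - E_b)/k_BT) and the rate ratio r_fb/r_bf = p_b/p_f.
# All energies are dimensionless multiples of k_BT; the free state carries
# the translational kinetic energy E_f = 3/2 k_BT (three degrees of freedom).

E_FREE_KBT <- 1.5

check_pb <- function(p_b) {
  if (any(!is.finite(p_b)) || any(p_b <= 0) || any(p_b >= 1))
    stop("`p_b` must lie strictly inside (0, 1): ",
         "the two-state energy diverges at p_b = 0 or 1")
}

#' Energy difference between the free and the bound state
#'
#' \deqn{\Delta E = E_f - E_b = k_BT \ln\left(\frac{p_b}{1-p_b}\right).}
#' Negative whenever the protein spends less than half its time bound.
#'
#' @param p_b Bound-state probability (time-share), strictly in (0, 1).
#' @return Delta E in units of k_BT.
#' @examples
#' energy_difference(0.5)    # 0
#' energy_difference(0.30)   # log(3/7) = -0.847
#' @export
energy_difference <- function(p_b) {
  check_pb(p_b)
  log(p_b / (1 - p_b))
}

#' Energy of the bound state
#'
#' \deqn{E_b = \frac{3}{2} k_BT - k_BT \ln\left(\frac{p_b}{1-p_b}\right),}
#' i.e. the free-state kinetic energy minus the occupancy-derived energy
#' difference. Strictly decreasing in `p_b`: stronger binders sit lower.
#'
#' @inheritParams energy_difference
#' @return E_b in units of k_BT.
#' @export
bound_state_energy <- function(p_b) {
  E_FREE_KBT - energy_difference(p_b)
}

#' Ratio of the free-to-bound and bound-to-free transition rates
#'
#' At equilibrium detailed balance gives
#' \deqn{\frac{r_{fb}}{r_{bf}} = \frac{p_b}{1-p_b};}
#' a ratio below 1 means unbinding is more likely than binding.
#'
#' @inheritParams energy_difference
#' @return Dimensionless rate ratio.
#' @export
rate_ratio <- function(p_b) {
  check_pb(p_b)
  p_b / (1 - p_b)
}

#' Invert an energy difference back to a bound probability
#'
#' @param delta_E Energy difference E_f - E_b in k_BT.
#' @return p_b = exp(delta_E) / (1 + exp(delta_E)).
#' @export
bound_probability <- function(delta_E) {
  stats::plogis(delta_E)
}

#' Two-state energetics per condition
#'
#' Converts the bound fractions of batch summaries into Boltzmann
#' energetics. `"per_point"` computes Delta E, E_b and the rate ratio for
#' every retained curve and averages them (mean +/- SD); `"of_mean"`
#' evaluates them once at the mean bound fraction. The two differ because
#' E_b is convex in p_b below 0.5 (Jensen), so per-point averages lie above
#' the of-mean value there; both are reported with the mode recorded.
#'
#' @param summaries A (named) list of `protein_summary` objects from
#'   [batch_analyze()] in `"on_pattern"` mode, or a single one.
#' @param averaging `"per_point"` or `"of_mean"`.
#' @return A data.frame with one row per condition: `p_b_mean`, `p_b_sd`,
#'   `deltaE_kBT` (+/- SD in per_point mode), `E_b_kBT`, `rate_ratio`,
#'   `n_curves`, `mode`. Curves with p_b outside (0, 1) are skipped with a
#'   warning.
#' @export
energetics_table <- function(summaries,
                             averaging = c("per_point", "of_mean")) {
  averaging <- match.arg(averaging)
  if (inherits(summaries, "protein_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    pb <- s$bound_fractions
    ok <- is.finite(pb) & pb > 0 & pb < 1
    if (any(!ok))
      warning(sprintf("condition '%s': %d bound fraction(s) outside (0,1) skipped",
                      s$condition, sum(!ok)))
    pb <- pb[ok]
    if (length(pb) == 0L)
      stop(sprintf("condition '%s': no usable bound fractions", s$condition))
    if (averaging == "per_point") {
      dE <- energy_difference(pb); Eb <- bound_state_energy(pb)
      rr <- rate_ratio(pb)
      data.frame(condition = s$condition,
                 p_b_mean = mean(pb), p_b_sd = stats::sd(pb),
                 deltaE_kBT = mean(dE), deltaE_sd = stats::sd(dE),
                 E_b_kBT = mean(Eb), E_b_sd = stats::sd(Eb),
                 rate_ratio = mean(rr), rate_ratio_sd = stats::sd(rr),
                 n_curves = length(pb), mode = averaging)
    } else {
      m <- mean(pb)
      data.frame(condition = s$condition,
                 p_b_mean = m, p_b_sd = stats::sd(pb),
                 deltaE_kBT = energy_difference(m), deltaE_sd = NA_real_,
                 E_b_kBT = bound_state_energy(m), E_b_sd = NA_real_,
                 rate_ratio = rate_ratio(m), rate_ratio_sd = NA_real_,
                 n_curves = length(pb), mode = averaging)
    }
  }))
}
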