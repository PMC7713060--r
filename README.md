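# svfcs

Fluorescence correlation spectroscopy (FCS) analysis of soluble proteins
that transiently bind a two-dimensional layer of immobilized synaptic
vesicles (SVs).

## The problem

Many presynaptic proteins are retained in the synaptic bouton, and a
leading explanation is that the dense SV cluster binds them. A minimalist
in vitro version of that environment — SVs patterned as a 2D layer on a
coverslip, with fluorescently tagged proteins diffusing above it — lets
FCS separate each protein's mobility into a fast freely diffusing pool and
a slow vesicle-bound pool. `svfcs` implements the full quantitative
pipeline for such experiments, plus synthetic-data generators with known
ground truth so every stage can be validated end to end:

- closed-form one- and two-component diffusion autocorrelation models,
- a software (multi-tau) correlator for photon-count traces,
- Brownian-dynamics simulation with two-state binding kinetics,
- Levenberg–Marquardt curve fitting, observation-volume calibration,
  aggregate-spike exclusion, and model selection,
- conversion of bound fractions into two-state Boltzmann energetics,
- spot-based vesicle density quantification of STED-like images,
- nonparametric group comparisons (Mann–Whitney, Kruskal–Wallis, post hoc).

## The model

Intensity fluctuations of fluorophores crossing a 3D-Gaussian confocal
volume (lateral waist `w0`, axial extent `z0`) decay as

    G(tau) = (gamma / N) * 1/(1 + tau/tau_D) * 1/sqrt(1 + (tau/tau_D) (w0/z0)^2)

with `G(0) = gamma/N` (`gamma` = 0.35 here), mean particle number `N`, and
diffusion time `tau_D = w0^2 / (4 D)`. Over the vesicle layer a
number-weighted two-component mixture describes the data,

    G2(tau) = (gamma / N^2) * (N1 g1(tau) + N2 g2(tau)),   N = N1 + N2,

whose slow component is the vesicle-bound pool; the bound fraction
`p_b = N2 / N` is the time-share a protein spends bound. Treating binding
as a two-state Boltzmann system with the free state carrying only
translational kinetic energy `E_f = 3/2 k_BT` gives

    dE = E_f - E_b = k_BT ln(p_b / (1 - p_b)),
    E_b = 3/2 k_BT - k_BT ln(p_b / (1 - p_b)),
    r_fb / r_bf = p_b / (1 - p_b).

## Worked example

Synthesize 25 noisy on-pattern curves at the alpha-synuclein preset
(free/bound diffusion 67 and 4 um^2/s, 15% bound), fit the two-component
model, and derive the interaction energetics:

```r
library(svfcs)
vol <- observation_volume(w0 = 0.31)    # calibrated beam waist, um
curves <- synthesize_preset("alpha-Synuclein-on-SV", "on_pattern",
                            n_curves = 25, seed = 2)
fits <- lapply(curves, fit_two_component, vol = vol)
fits[[1]]
#> two-component FCS fit (converged)
#>   N1 = 1.677, N2 = 0.3071, tau_D1 = 0.0003388 s, tau_D2 = 0.005905 s
#>   D_free = 70.92, D_bound = 4.069 um^2/s, bound fraction = 0.155
#>   RSS = 0.05094 over 160 lags

summaries <- batch_analyze(list("alpha-Synuclein-on-SV" = curves), vol,
                           mode = "on_pattern")
summaries[[1]]
#> Condition 'alpha-Synuclein-on-SV' (on_pattern): 25 curves (0 excluded)
#>   D_free = 67 +/- 3.5, D_bound = 4.01 +/- 0.16 um^2/s, % bound = 15.1 +/- 0.8

energetics_table(summaries, averaging = "per_point")[, c(1, 4, 6, 8)]
#>                 condition deltaE_kBT  E_b_kBT rate_ratio
#>     alpha-Synuclein-on-SV  -1.729977 3.229977  0.1776539
```

The fitted means recover the generating values: the protein diffuses
freely at ~67 um^2/s, slows ~17-fold while bound, spends ~15% of its time
on the vesicles, and the bound state lies ~1.7 k_BT above the free state
in occupancy terms (negative `dE`: binding must pay an entropic penalty,
so unbinding is ~5.6x more likely than binding).

The same interfaces drive the other stages, e.g.
`run_pipeline(run_config(...), mode = "density", out_dir = "out")` for
vesicle-density quantification of a simulated STED field.

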