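---
title: "Models, estimators and design choices in svfcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in svfcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfcs)
```

`svfcs` analyzes fluorescence correlation spectroscopy (FCS) measurements
of soluble proteins that transiently bind a 2D layer of immobilized
synaptic vesicles. This vignette is the package's own account of the
models it implements, the tunable parameters that matter, what the
synthetic-data generators do and do not emulate, and the design choices
made where the design was genuinely open.

## Diffusion models and units

All lengths are in micrometers, times in seconds, diffusion coefficients
in um^2/s. The observation volume is the 3D-Gaussian detection profile

$$W(\mathbf r) = \exp\!\left(-\frac{2(x^2+y^2)}{w_0^2} - \frac{2z^2}{z_0^2}\right),$$

parameterized by the lateral waist $w_0$, axial extent $z_0$ and the
illumination-profile factor $\gamma$ relating the zero-lag amplitude to
the mean particle number, $G(0) = \gamma/N$. Defaults: $\gamma = 0.35$
(an instrument property, never fitted; for the ideal profile above
$\gamma = 2^{-3/2} \approx 0.354$) and structure parameter $z_0/w_0 = 5$,
a typical confocal elongation. The structure parameter is held fixed
during fits: it is barely identifiable from single-species curves and
letting it float mostly absorbs noise. $w_0$ comes from calibration
against a reference dye of known diffusion coefficient
(`calibrate_volume()`, e.g. Atto 488 at 400 um^2/s), via the diffusion
time

$$\tau_D = \frac{w_0^2}{4D}.$$

This quadratic form is the dimensionally consistent one and reproduces
the standard calibration numbers ($w_0 = 310$ nm with a 400 um^2/s dye
gives $\tau_D = 6.00625\times 10^{-5}$ s).

The two-component model is a *number-weighted* mixture,
$G_2(\tau) = \gamma N^{-2} (N_1 g_1 + N_2 g_2)$, which assumes equal
molecular brightness of the free and bound species — appropriate when
both carry the same single fluorescent tag. The bound fraction is
estimated as $p_b = N_2/(N_1+N_2)$ without a brightness correction.

## The software correlator

`autocorrelate_linear()` is the quadratic-cost oracle:
$g(k) = \overline{F_t F_{t+k}} / (\bar F_{\mathrm{direct}}
\bar F_{\mathrm{delayed}}) - 1$ at every multiple of the sampling
interval. The symmetric normalization (separate running means of the
direct and delayed samples) suppresses the bias that a single global mean
leaves at long lags on 30-s acquisitions. `autocorrelate_multitau()`
reproduces these values *exactly* on its first block (16 unbinned
channels by default) and then doubles the bin width per block by pairwise
summation, giving the quasi-logarithmic grid of hardware correlators at
linear cost. Rebinning acts as triangular averaging of the underlying
correlation, so coarse-level values deviate from the brute-force
estimator by a bounded, documented amount; the default lag range stops at
one tenth of the trace duration because the estimator variance explodes
beyond that. Optional per-lag standard errors come from splitting the
trace into 10 contiguous segments and taking the spread of segment
estimates.

## Synthetic data with known ground truth

`simulate_trace()` integrates independent Gaussian random walks
(per-axis step variance $2D(\text{state})\,dt$) in a periodic box at
least $6\times(w_0, w_0, z_0)$, with per-step two-state Markov switching
($P = r\,dt$, validity guard $r\,dt \le 0.1$) between a free state
($D_{\text{free}}$) and a bound state that remains mobile
($D_{\text{bound}} > 0$, matching the measured slow-but-nonzero bound
mobility of ~2 um^2/s). Detected intensity is a background plus
$W(\mathbf r)$ summed over particles, with Poisson photon noise. The
time step must keep the per-step RMS displacement under $w_0/5$.
Switching is spatially homogeneous — whether binding is confined to the
vesicle layer is not resolved by the data this emulates; a spatially
resolved variant would be an extension.

Two finite-size effects matter when validating the simulator against the
closed-form model. First, the amplitude convention: for the ideal
profile, $G(0) = 1/(C\,\pi^{3/2} w_0^2 z_0)$ at concentration $C$, which
equals $\gamma/N$ for $N = C\,(\pi/2)^{3/2} w_0^2 z_0$
(`effective_particle_number()`); uncorrelated background light further
dilutes the amplitude by $(\mu_{\text{sig}}/\mu_{\text{tot}})^2$.
Second, a closed periodic box conserves particle number, which depresses
the normalized ACF by roughly $1/M$ for $M$ particles in the box; the
validation tests therefore use $M = 60$, where the effect is below the
ensemble noise. The oracle comparison in the test suite uses six 5-s
traces at $D = 5$ um^2/s — sizes chosen so the ensemble standard error is
a few percent of the amplitude.

`synthesize_acf()` is the fast generator used for fitting studies: the
exact model on a log-spaced lag grid (160 points over 2 us – 1 s),
multiplied by $(1+\varepsilon)$ with $\varepsilon$ a stationary AR(1)
series across the lag index (marginal SD = `noise_fraction`, neighbour
correlation 0.8). The lag correlation mimics the smooth wiggles of real
finite-acquisition ACF estimates rather than white noise; the noise is
multiplicative because normalized ACF estimator errors scale with the
curve; and it is unbiased by construction, so ensemble means converge to
the model. Neither generator models photophysics (triplet dynamics,
bleaching), detector afterpulsing, or near-surface artefacts — passing
tests validate the estimators under Brownian motion with binding, not
those instrument effects.

`simulate_sted_image()` renders a hard-core point process (Poisson count
at the requested areal density, sequential placement with bounded
rejection at the minimum separation) as Gaussian point-spread functions
over a Poisson background. Defaults emulate a super-resolution image of
an immobilized vesicle layer: 20-nm pixels, 60-nm PSF FWHM, 120-nm hard
core, peak 150 counts over background 5.

## Fitting

Levenberg–Marquardt (via `minpack.lm`) is local and the two-component
objective has local minima, so fits are multi-started: diffusion times on
a coarse log grid across the lag range (3 per decade for one component, 2
per decade in ordered pairs with ratio >= 3 for two), per-species
amplitudes solved *linearly* at each grid point (the model is linear in
the amplitudes given the taus), and the best three starts polished by LM.
Bounds keep fits identifiable: $N \in [10^{-3}, 10^4]$, $\tau_D$ within
the lag range; a parameter landing on a bound flags the result rather
than failing silently. Standard errors come from the Jacobian at the
optimum. After convergence the components are put in canonical order
(species 1 fast = free), so reported results always satisfy
$D_{\text{free}} > D_{\text{bound}}$; fits whose diffusion times differ
by less than a factor 3 are flagged `unresolved`.

**Weighting.** The default objective minimizes *relative* residuals
(weights $1/G$). Normalized ACF estimator noise is predominantly
multiplicative, and an unweighted fit concentrates all its leverage on
the first decade of lags where the curve is large; for weakly separated
components (diffusion-time ratio ~5) that leaves the slow component
poorly constrained and visibly biases its recovered diffusion
coefficient and the bound fraction upward. Relative weighting is the
variance-matched objective under this noise model, keeps the problem
conditioned across lag decades, and recovers all preset parameters
without detectable bias. Unweighted (`weights = NULL`) and
inverse-standard-error (`weights = "se"`) objectives remain available.

**Model selection.** Whether a curve needs one or two components is
decided by a nested-model F-test at $\alpha = 0.05$, guarded twice: the
two-component fit must be resolved (ratio >= 3), and its minor component
must carry at least 5% of the number fraction. The second guard exists
because, under smooth lag-correlated noise, the F-test alone accepts
spurious second components that absorb noise with negligible or
implausibly extreme fractions; 5% sits safely below the smallest
physically measured bound pool (~10%). With both guards, single-species
curves at 2% noise select "one" in well over 95% of cases while strongly
separated mixtures always select "two".

**Aggregate exclusion.** Acquisitions contaminated by bright slow
aggregates are excluded before fitting: the trace is rebinned to 10-ms
bins and rejected when bins exceed median + 10 MAD for at least 3
consecutive bins (strict inequality, so values exactly at the threshold
are kept). All three constants are declared defaults — the underlying
experimental practice is a manual judgement — and are configurable and
logged in the result.

## Energetics

With occupancies $p_b + p_f = 1$, Boltzmann statistics give
$\Delta E = k_BT \ln(p_b/p_f)$, $E_b = \tfrac32 k_BT - \Delta E$ (the
free state carries only translational kinetic energy, three degrees of
freedom), and the detailed-balance rate ratio $r_{fb}/r_{bf} = p_b/p_f$.
Energies are reported as dimensionless multiples of $k_BT$; no absolute
temperature handling. The occupancy endpoints $p_b \in \{0, 1\}$ are
domain errors (the energy diverges), not clamped values.

`energetics_table()` offers two averaging modes because the choice is
genuinely ambiguous when summarizing many curves: `per_point` evaluates
the energetics on every curve and averages (mean ± SD), `of_mean`
evaluates once at the mean occupancy. They differ by Jensen's inequality
— $E_b$ is convex in $p_b$ below 0.5, so per-point averages sit above
the of-mean value (for a 30% bound pool, $E_b$ at the mean is 2.347
$k_BT$ while per-measurement averaging lands higher). Neither is
asserted to be "the" published procedure; the mode is recorded in the
output.

## Vesicle density from images

The image pipeline makes an "empirically defined threshold" explicit and
reproducible. A difference-of-Gaussians bandpass (sigmas 0.5 and 3 times
the PSF sigma) removes pixel noise and slow background while passing
diffraction-limited spots. Detection thresholds local maxima at
median + 5 MAD of the *filtered* image: the robust scale estimate tracks
the background noise rather than the spot signal, which matters on
densely covered fields (at 15 spots/um^2 a mean + 5 SD threshold sits
just below the peak amplitude and silently discards half the spots).
Non-maximum suppression uses a radius of one PSF FWHM (0.06 um default),
and positions are refined by an intensity-weighted centroid over the 3x3
neighbourhood, giving subpixel, translation-invariant positions.

Density is the spot count over the image area. Spacing is reported as
the *mean nearest-neighbour distance* and labelled as such: "distance
between centres" admits several pairwise statistics, and a Poisson
process at 15 um^-2 already has a nearest-neighbour mean of
$1/(2\sqrt{15}) \approx 129$ nm, so no equality with any particular
printed spacing is asserted.

## Group statistics

`mann_whitney_u()` uses midrank ties throughout; for $n_1+n_2 \le 12$
the p-value is exact by enumerating all group assignments of the pooled
midranks (the reference implementation refuses exact p-values under
ties), otherwise the tie-corrected normal approximation is used.
`kruskal_wallis()` delegates to the standard tie-corrected H test and
defines the degenerate all-identical case as H = 0, p = 1. Two post-hoc
variants are provided because "Tukey's post hoc after Kruskal–Wallis" is
not a standard rank procedure: Dunn's z-tests on mean ranks (default,
Holm-adjusted) and Tukey's HSD applied to rank-transformed data, with
the method recorded in the output.

## Presets and study conditions

`sv_presets()` fixes the simulation presets to the published per-protein
values: bulk diffusion coefficients, bound-pool diffusion coefficients
and bound percentages for twelve conditions, plus the two antibody
controls and the on-pattern alpha-synuclein pair (free 67, bound 4
um^2/s). The antibody control curves were published without a bound
percentage, so those presets need one number the data do not provide:
30% for the interacting (anti-goat) antibody and 20% for the confined
anti-rat component — amplitudes typical of a strong and a weak slow
component respectively, chosen once and not tuned; only the diffusion
coefficients of these presets are treated as generating truths to
recover. Default synthesis uses 25 curves per condition at 2% noise,
matching a realistic per-pattern acquisition set.

## Known limitations

- No triplet/blinking terms, anomalous-diffusion exponents, or scanning
  FCS variants; curves dominated by photophysics will fit poorly.
- The bound fraction assumes equal brightness of free and bound species.
- The closed periodic simulation box slightly depresses ACF amplitudes
  (~1/M); use enough particles when validating amplitudes.
- The hard-core image generator is not a cluster process; images of
  aggregated vesicles will be harder than the tests suggest.
- Exact p-values are enumerated only up to 12 pooled observations;
  beyond that the normal approximation's accuracy is the usual one.
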