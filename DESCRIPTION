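Package: svfcs
Title: Fluorescence Correlation Spectroscopy of Protein Binding to
    Synaptic-Vesicle Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for fluorescence correlation
    spectroscopy (FCS) measurements of soluble proteins that transiently bind
    a two-dimensional layer of immobilized synaptic vesicles. Provides
    closed-form one- and two-component diffusion autocorrelation models, a
    software multi-tau correlator for photon-count traces, Brownian-dynamics
    simulation with two-state binding kinetics, Levenberg-Marquardt curve
    fitting with observation-volume calibration and aggregate-spike
    exclusion, conversion of bound fractions into two-state Boltzmann
    interaction energies and transition-rate ratios, spot-based vesicle
    density quantification of super-resolution images, and nonparametric
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tiff,
    yaml,
    EBImage,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
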