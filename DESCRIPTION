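Package: fcsfit
Title: Simulation, Correlation and Model Fitting for Fluorescence
    Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative fluorescence correlation spectroscopy
    (FCS) and fluorescence-intensity quantification. Simulates photon-count
    traces of fluorophores diffusing through a 3D Gaussian confocal
    observation volume (with triplet blinking) by Brownian dynamics,
    computes fluctuation autocorrelation curves by direct and multi-tau
    schemes, fits the one-component three-dimensional diffusion model with
    triplet state, calibrates the observation volume from a reference dye,
    and derives diffusion coefficients and molar concentrations. Also
    generates synthetic cell images and implements background-subtracted
    per-cell intensity quantification for ranking promoter strength.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
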