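Package: pesrs
Title: Single-Molecule Analysis of Plasmon-Enhanced Stimulated Raman
    Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hyperspectral plasmon-enhanced stimulated
    Raman scattering (PESRS) microscopy at single-molecule sensitivity.
    Provides a ground-truthed synthetic scene generator for nanoparticle
    aggregate substrates, adaptive iteratively reweighted penalized least
    squares (airPLS) baseline removal over a Whittaker smoother,
    spatial-spectral block-matching collaborative denoising, multivariate
    curve resolution by alternating least squares (MCR-ALS) with
    non-negativity for bianalyte isotopologue unmixing, single-molecule
    event selection and ratio-histogram statistics with an analytic Poisson
    hot-spot occupancy model, Fano line-shape fitting and bandwidth
    analysis, and classification of blinking and single-step bleaching in
    time-lapse stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
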