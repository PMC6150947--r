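Package: meshbench
Title: Benchmarking MEG Source Reconstruction with Distorted Cortical Mesh Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for quantifying the anatomical discrimination of
    magnetoencephalography (MEG) source-reconstruction algorithms using
    resting-state-like data. Sensor recordings are partitioned into
    quasi-stationary network states with a hidden Markov model, inverted onto
    libraries of progressively distorted cortical meshes built by weighted
    Fourier series (spherical-harmonic) surface decomposition, and scored by
    held-out-channel cross-validation and variational free energy under four
    empirical-Bayes source-covariance priors (minimum norm, LORETA-like,
    empirical Bayesian beamformer, multiple sparse priors). The highest
    distinguishable harmonic is converted to a millimetre resolution estimate
    via corresponding-vertex distances. Includes a synthetic-data generator
    (folded cortex meshes, sensor caps, state-switching source activity,
    calibrated sensor noise) and a single-sphere analytic forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
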