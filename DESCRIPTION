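Package: ppgsim
Title: Synthetic Photoplethysmography from Layered-Tissue Monte Carlo to
    Blood-Pressure Algorithm Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end generation and analysis of synthetic volar-fingertip
    photoplethysmography (PPG). A weighted Monte Carlo photon-transport engine
    over a six-layer optical skin model yields pulsatile (AC) and baseline (DC)
    signal amplitudes as a function of subject age, epidermal melanosome volume
    fraction and device wavelength. Three-Gaussian pulse templates are fitted
    and tiled into continuous records, sinusoidal noise is injected, and a
    device simulator applies IIR filter chains, ADC quantization and rescaling.
    Pulse-wave-analysis feature extraction (systolic/diastolic widths, dicrotic
    notch, areas) and a model-agnostic regression harness measure how
    blood-pressure predictors respond to the simulated patient and device
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    nnet,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
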