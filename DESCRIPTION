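Package: mossddpg
Title: Multi-Observation Single-Step Deep Deterministic Policy Gradient
    for Sensorless Adaptive Optics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and control toolkit for image-metric-based
    sensorless adaptive optics on a confocal scanning laser
    ophthalmoscope.  Provides a Fourier-optics image-formation model
    (Noll-indexed Zernike wavefronts, double-pass effective point spread
    function with a multimode-fiber detector), random aberration
    generators, a single-step reinforcement-learning environment built on
    2N+1 image-sharpness observations, an LSTM actor-critic agent trained
    by single-step deterministic policy gradient, model-based comparators
    (parabolic maximization and Zernike-mode hill climbing), and a Monte
    Carlo benchmark harness for residual RMS wavefront error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
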