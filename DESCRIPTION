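Package: spikecal
Title: Ground-Truth Calibration and Benchmarking of Spike Rate Inference
    from Calcium Imaging
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to calibrate and benchmark spike rate inference from
    calcium imaging of spinal cord (and similar) neurons against paired
    electrophysiological ground truth. Provides S4 containers for paired
    fluorescence/spike recordings, a synthetic ground-truth generator with
    the spike-pattern and kernel statistics of dorsal horn neurons,
    standardized noise levels and noise/frame-rate resampling, calcium
    response kernel extraction by regularized deconvolution with
    exponential fits, three inference approaches (a supervised
    convolutional network with leave-one-out retraining, non-negative
    AR(1) deconvolution, and raw dF/F as a proxy), and the full evaluation
    suite: shift-optimized correlations, false positive/negative curves
    over evaluation windows, segment comparisons, high-frequency spike
    event analysis, and rate-variability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
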