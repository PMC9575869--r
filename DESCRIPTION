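Package: harpipe
Title: Kinematic-Static Pattern Recognition for Wearable Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting physical human motion from
    fused wearable-sensor recordings (tri-axial IMU plus physiological
    channels such as sEMG and ECG/heart rate). Provides a synthetic
    multi-sensor recording generator, a three-phase calibration-based IMU
    filter (still-interval bias estimation, wavelet gyroscope denoising and a
    gradient-descent quaternion orientation filter), a reverse-Bessel-polynomial
    low-pass filter for physiological channels, time-based stream fusion with
    overlapping 2-second windows, a polynomial probability-density decision
    that splits windows into kinematic and static motion patterns,
    pattern-specific feature extraction (dynamic time warping and Gaussian
    Markov random field moments for kinematic windows; multisynchrosqueezing
    transform and hidden Markov random field energies for static windows),
    feature optimization by quadratic discriminant scores and orthogonal fuzzy
    neighborhood discriminant analysis, and semi-supervised classification by
    manifold regularization (RLS, Laplacian RLS, and Nystrom-preconditioned
    conjugate-gradient Laplacian RLS) with full evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
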