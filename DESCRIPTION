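Package: sleepmat
Title: Sleep Posture Detection from Sparse Piezoelectric Mat Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of 32-channel piezoelectric pressure-mat
    recordings for unobtrusive sleep posture monitoring. Provides a calibrated
    synthetic-signal generator (sinusoidal respiration, amplitude-modulated
    ballistocardiogram, motion-artifact bursts), linear-phase FIR decomposition
    into respiratory, cardiac and deviation components, entropy-based motion
    artifact detection, model-based extraction of cardiorespiratory activity
    intensity maps and beat-to-beat temporal features, a four-branch
    spatiotemporal convolutional network for supine/lateral posture
    classification, and subject-grouped cross-validation with summed confusion
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    nnet,
    pROC,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
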