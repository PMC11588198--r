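Package: murmurscan
Title: Heart-Sound Segmentation and Systolic Murmur Detection from
    Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments phonocardiogram (PCG) recordings into the fundamental
    heart-sound states (S1, systole, S2, diastole) and detects and types
    systolic murmurs.  A bidirectional GRU frame classifier turns a z-scored
    log-spectrogram into per-frame state posteriors; four competing
    duration-explicit hidden semi-Markov models then decode the posteriors
    under different assumptions about murmur timing (none, holosystolic,
    early-systolic, mid-systolic).  Comparing the segmentation confidences of
    the four decoders yields a murmur decision, a murmur likelihood and a
    signal-quality estimate, which feed a patient-level murmur rule and a
    gradient-boosted classifier of clinical outcome.  Includes a seeded
    synthetic PCG and cohort generator, evaluation metrics for the murmur and
    outcome tasks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
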