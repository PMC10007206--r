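Package: jitterhrv
Title: Timing-Jitter Sensitivity of HRV-Based Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation pipeline quantifying how Gaussian timing jitter in
    heartbeat detection degrades heart-rate-variability (HRV) features and
    HRV-based sleep-stage classification. Provides a synthetic polysomnography
    cohort generator (hypnograms and R-peak streams with stage-dependent RR
    dynamics), hypnogram cleaning and micro/macro relabeling, a calibrated
    97-level jitter severity ladder, Lomb-Scargle spectral HRV features on
    unevenly sampled heartbeat-interval series, per-participant cross-validated
    sleep staging with kNN-based Bayes-error bounds and feature sensitivity
    slopes, and a conservative triangle-inequality upper bound on
    ballistocardiogram-versus-ECG beat timing error from paired beat tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    class,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
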