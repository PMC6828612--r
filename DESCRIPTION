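Package: peritheta
Title: Peri-Error Reaction-Time Dynamics and Frontal Midline Theta Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peri-error reaction-time dynamics and
    error-related frontal midline theta (4-8 Hz) EEG power in two-group
    (e.g., ADHD vs typically developing) forced-choice experiments.
    Classifies trials around isolated commission errors, standardizes
    reaction times against error-free trials, fits maximum-likelihood
    random-intercept linear and logistic mixed models compared by
    likelihood-ratio tests, and computes Hann-tapered moving-window FFT
    time-frequency representations with trial-wise pre-prime dB baseline
    correction and fronto-central theta summaries. Includes a synthetic
    two-group cohort generator (behavioral trial tables plus continuous
    multichannel EEG with 1/f background, eyeblinks, line noise and
    calibrated response-locked theta bursts) so every stage is testable by
    parameter recovery, a minimal 16-bit EDF writer/reader, and a
    noncentral-t power analysis for two-sample designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
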