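Package: forcetrack
Title: Tool-Tissue Interaction Force Analytics for Surgical Performance
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analytics pipeline for two-prong (bipolar forceps)
    tool-tissue interaction force recordings from the operating room.
    Segments annotated force recordings into task episodes, smooths them
    with a zero-phase Butterworth low-pass filter, removes outlier
    segments by expert-derived 1st/99th percentile thresholds, computes a
    catalogue of 37 hand-crafted time-series features per segment (moments,
    peaks, spectral entropy, stationarity and nonlinearity statistics,
    windowed shift statistics, autocorrelation summaries), screens features
    with two-way ANOVA (experience by task), trains an expert-versus-novice
    skill classifier (PCA plus radial-kernel SVM) and a five-class surgical
    task recogniser (single-layer LSTM network), and reports per-surgeon
    performance gauges against an expert baseline. Includes a seeded
    generator of task- and experience-conditioned synthetic force segments
    for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    e1071,
    jsonlite,
    pROC,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
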