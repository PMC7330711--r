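Package: aecnet
Title: Orthogonalized Envelope-Correlation Connectomes and Community Graph
    Statistics for Band-Limited Neural Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Band-specific resting-state functional connectivity from
    region-of-interest source time series: zero-phase band-pass filtering and
    analytic-signal construction, leakage-robust orthogonalized
    amplitude-envelope correlation with sliding-window median aggregation,
    proportional thresholding and binarization of connectivity matrices,
    hemisphere-resolved resting-state-network community edge counting, and the
    accompanying group and symptom statistics (pooled-variance t tests,
    summary-statistic t reproduction, Spearman rank correlations). Includes a
    synthetic cohort generator that plants band-limited envelope coupling,
    instantaneous source-leakage mixing, group effects, and clinical scores
    linked to planted coupling, so the whole pipeline is testable without
    access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
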