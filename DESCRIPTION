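Package: eegstability
Title: Effect-Size Stability Analysis for Resting-State EEG Feature Batteries
Version: 0.1.0
Authors@R: person("EEG Stability", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulates epoched resting-state EEG cohorts with configurable
    demographic effects, extracts a 726-variable battery of spectral,
    aperiodic, peak-alpha, phase-amplitude coupling, multiscale entropy and
    inter-site phase clustering features, and evaluates group differences with
    type-III partial eta-squared regression models, stratified split-half
    replication rates, and sample-size/normalised-mutual-information
    bootstrap analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    digest
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
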