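Package: rtquic
Title: RT-QuIC Fluorescence Kinetics Analysis and Diagnostic Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for real-time quaking-induced conversion
    (RT-QuIC) seed-amplification assays. Reads plate-reader Thioflavin T
    fluorescence time series and plate maps, performs baseline estimation
    over a sliding window, percent-of-maximum normalization, noise-floor
    threshold computation, replicate-level threshold-crossing and lag-time
    estimation, and sample-level positivity calling under a
    two-of-four-replicates rule with a fixed cutoff time. Provides
    diagnostic-accuracy statistics for assay evaluation (sensitivity and
    specificity with exact Clopper-Pearson intervals, two-sided Fisher's
    exact test, Cramer's V, exact McNemar test, Cohen's kappa, and
    either-positive combination of two tests) and a deterministic
    synthetic seeding-kinetics generator so the whole pipeline can be
    exercised and validated without access to raw assay exports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
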