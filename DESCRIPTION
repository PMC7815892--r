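Package: imputeBench
Title: Spike-In Benchmarking of Missing-Value Imputation for Label-Free
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic three-species spike-in protein abundance
    benchmarks with designed intergroup ratios, simulates missing values
    with controlled total and missing-not-at-random (MNAR) rates, imputes
    them with seven methods (lowest of detection, downshifted normal,
    k-nearest neighbours, local least squares, iterative random forest,
    iterative SVD and Bayesian PCA), and scores imputation accuracy by
    normalized root mean square error on abundances and intergroup
    ratios, differential-expression true positives, false altered-protein
    discovery rate and ROC curves over a grid of missingness conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
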