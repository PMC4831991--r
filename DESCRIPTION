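Package: peakpipe
Title: Processing and Benchmarking of UHPLC-MS Metabolomics Peak Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing non-targeted UHPLC-MS metabolomics peak
    tables (feature filtering, probabilistic quotient and sum normalisation,
    six missing-value imputation methods, generalised-logarithm and related
    transformations, four feature scalings) and for benchmarking every
    permutation of those processing choices against spike-in ground truth
    using univariate screens, NIPALS principal component analysis and
    partial least squares discriminant analysis. Includes a synthetic
    two-class peak-table generator with pooled quality-control replicates,
    controllable missingness and a spike-in constructor, plus an NRMSE
    harness for comparing imputation methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
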