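Package: strokeconn
Title: Lesion Volume and Resting-State Network Connectivity Models of
    Acute Stroke Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling acute stroke severity (NIHSS) from lesion
    volumetrics and seed-based resting-state functional connectivity.
    Provides lesion volume quantification from binary masks, band-pass
    filtering and ROI time-series extraction, Fisher z-transformed intra-
    and inter-network connectivity features over lateralized network
    configurations, incremental cross-validated linear modelling with
    collinearity screening, a nested model-comparison toolkit (paired fold
    t-tests, likelihood-ratio tests, AIC differences), and a synthetic
    cohort generator with block-structured network covariance for testing
    the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
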