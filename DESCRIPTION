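Package: cvdnotes
Title: Identify Cardiovascular Hospitalisations from Diabetes Visit Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for phenotyping prior
    cardiovascular-disease (CVD) hospitalisations from the free-form text of
    diabetes routine visits. Links visit tables to hospital discharge
    registries by ICD-9-CM code under infinite, 24-, 12-, and 6-month
    look-back windows, preprocesses Italian clinical text (stop-word removal,
    Snowball stemming, rare-word pruning), trains a bidirectional-LSTM text
    classifier, calibrates single- and double-threshold (reject-option)
    decision rules against a target uncertainty level, and evaluates by-visit
    and by-patient performance under class imbalance. Ships a synthetic
    electronic-health-record generator so the whole analysis runs without
    access to proprietary clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    lubridate,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
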