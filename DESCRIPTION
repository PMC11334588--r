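Package: dtainterim
Title: Exact Group Sequential Interim Analysis for Diagnostic Accuracy Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plan and evaluate interim analyses of diagnostic test accuracy
    (DTA) studies with co-primary sensitivity and specificity endpoints.
    Implements an adaptation of the exact group sequential method in which
    the false-negative and false-positive rates are monitored against
    stagewise failure-count boundaries anchored to the planned final sample
    size, supporting early termination for futility (and, optionally,
    efficacy). Provides interim scheduling by total participants or by
    disease-positive cases, exact operating characteristics by binomial
    convolution, sample size re-estimation from observed prevalence, a
    synthetic DTA cohort simulator with Monte Carlo operating
    characteristics, and report rendering of boundary and decision tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
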