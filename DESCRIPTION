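Package: jaderpv
Title: Signal Detection and Time-to-Onset Analysis for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous
    adverse-event reporting databases laid out in the JADER three-table
    schema (Drug, Reaction, Demographic). Provides report ingestion and
    cleaning, Standardized MedDRA Query style case definitions,
    disproportionality screening by reporting odds ratio with
    Haldane-Anscombe correction and Fisher's exact test, volcano-plot
    coordinates, continuity-corrected time-to-onset computation with
    JADER date-dialect cleaning, two-parameter Weibull maximum-likelihood
    fitting with failure-pattern classification, stratified group
    comparisons, and a seeded synthetic-report generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
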