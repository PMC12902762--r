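Package: tierscreen
Title: Tiered Adaptive Mental-Health Screening and Diagnostic Test Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-tier adaptive screening procedure for common
    mental disorders (depression, anxiety, posttraumatic stress, insomnia)
    built from five validated symptom scales with gateway cutoffs and
    short-form item carry-over. Provides a stateful administration engine,
    retrospective tier simulation over complete response data with
    item-burden accounting and per-tier culling reports, diagnostic test
    accuracy metrics (sensitivity, specificity, predictive values, accuracy
    with Wald confidence intervals) and Cohen's kappa against a reference
    standard, and a seeded generator of synthetic cohorts with correlated
    latent severities, ordinal item responses and diagnosis labels so the
    whole pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
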