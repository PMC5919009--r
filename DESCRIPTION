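Package: mpescreen
Title: Multivariate Screening and Subtype-Specific Risk Models for Matched
    Molecular-Epidemiology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating exposure biomarkers and germline variants to
    the risk of mutually exclusive molecular tumor subtypes in matched
    case-control studies. Provides a synthetic matched-cohort generator with
    known ground-truth effects; control-based discretization and per-SD
    standardization; discrete Bayesian-network structure learning by
    hill-climbing on an AIC score with bootstrap model averaging and an
    estimated edge-inclusion threshold; conditional logistic regression over
    matched sets with subtype-specific odds ratios and heterogeneity
    likelihood-ratio tests; inverse-probability-weighted conditional logistic
    regression for tumor-data selection bias; and case-case multinomial
    ratio-of-odds-ratios models. A single orchestrator runs the full
    two-step analysis reproducibly from one seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
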