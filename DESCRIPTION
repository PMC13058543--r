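Package: sacts
Title: Chest Trauma Scores and Exact Contingency-Table Inference for
    Blunt Chest Trauma Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculators for the conventional chest trauma score (C-CTS)
    and the X-ray-only South African chest trauma score (SA-CTS), exact
    inference for 2x2 and r x c contingency tables under the
    margin-fixed noncentral hypergeometric model (two-sided Fisher
    p-values, conditional maximum-likelihood odds ratios, exact
    tail-inversion confidence intervals), score-cutpoint analysis for
    dichotomised risk scores, and a seeded synthetic cohort generator
    with a logistic score-to-outcome link for end-to-end testing of the
    risk-stratification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
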