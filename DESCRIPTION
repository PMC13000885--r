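Package: gfrmon
Title: Longitudinal Monitoring Accuracy of GFR Estimating Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating how well serum creatinine and cystatin C
    based estimates of glomerular filtration rate (GFR) track change in
    measured GFR over time in moderate chronic kidney disease. Implements
    eight published CKD-EPI and EKFC estimating equations behind a
    declarative coefficient registry, KDIGO G-category staging and the
    combined ">=25% decline plus category drop" progression classifier,
    annualised slope estimation (two-point, per-individual least squares,
    and mixed-effects with participant-level random slopes), large-error
    agreement statistics with exact binomial confidence intervals, McNemar
    paired comparisons, diagnostic accuracy (sensitivity, specificity,
    predictive values), P30 and median bias summaries, and a seeded
    synthetic longitudinal cohort generator for end-to-end validation
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
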