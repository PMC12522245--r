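Package: pasenorms
Title: Age- and Sex-Specific Normative Percentiles for the PASE
    Physical-Activity Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing normative percentile values for the
    Physical Activity Scale for the Elderly (PASE): questionnaire scoring
    with configurable activity weights, eligibility filtering of a
    'healthy' reference sample, four-parameter distributional regression
    (sinh-arcsinh, skew exponential power, Johnson SU and skew-t families)
    with age-smoothed parameter curves ranked by generalized AIC,
    per-percentile quantile regression with linear, polynomial, smoothed
    and fractional-polynomial bases, repeated age-stratified
    cross-validation of holdout centile coverage, and generation of norm
    tables and charts with score-to-percentile lookup. Includes a
    synthetic-cohort generator with closed-form ground-truth centiles so
    the whole pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
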