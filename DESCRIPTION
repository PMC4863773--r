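Package: hfcea
Title: Markov Cohort Cost-Effectiveness Modelling of Eplerenone in NYHA
    Class II Chronic Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state (NYHA I-IV plus dead) Markov cohort model for the
    cost-effectiveness of eplerenone versus usual care in chronic heart
    failure with mild (NYHA Class II) symptoms, from an Australian healthcare
    system perspective in 2014 AUD. Implements hazard-ratio transformation of
    per-cycle transition probabilities, a spironolactone/placebo usual-care
    mixture, age-trend mortality scaling, discounted accrual of life-years,
    quality-adjusted life-years and costs, incremental cost-effectiveness
    ratios, number needed to treat, one-way deterministic sensitivity
    analysis, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, pre-registered scenario analyses, and a
    patient-level microsimulator with multinomial transition-table estimators
    that serves as the package's independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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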