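Package: saeprev
Title: Small-Area Estimation and External Validation of Survey Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate category prevalences (e.g. smoker, ex-smoker,
    never smoker) for small areas defined by region, sex and age group, and to
    validate model-based estimates against design-based direct estimates from
    an independent survey. Implements the survey-weighted ratio (Hajek) direct
    estimator with Taylor-linearized variance, a mixed multinomial logit
    small-area model with per-category Gaussian random area effects fitted by
    Laplace-approximated maximum likelihood, parametric-bootstrap mean squared
    errors, and a concordance protocol based on the one-way absolute-agreement
    intraclass correlation coefficient with F-based confidence intervals, Wald
    intervals for between-method differences, and coefficient-of-variation
    screening. A seeded synthetic-data generator emulates paired national and
    regional survey microdata with unequal sampling weights so the whole
    pipeline is testable without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), nnet, jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
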