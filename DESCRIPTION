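Package: phacorisk
Title: Exhaustive Feature-Subset Discriminant Analysis of Cataract
    Surgery Complication Risk
Version: 0.1.0
Authors@R:
    person("phacorisk", "developers", email = "phacorisk@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for studying intraoperative
    complication risk in phacoemulsification cataract surgery from
    patient-level tabular data. Implements five Gaussian discriminant
    classifier variants (linear, diaglinear, quadratic, diagquadratic,
    mahalanobis) from their density formulas, balanced-undersampling
    repeated-randomization evaluation with accuracy / specificity /
    sensitivity aggregation, exhaustive feature-subset search with
    feature-occurrence scoring, and a single-hidden-layer
    backpropagation network for predicting surgery time. Because no
    clinical cohort is deposited, the package ships a calibrated
    synthetic-cohort generator emulating the published population
    marginals, complication prevalence and surgeon-stratified risk, so
    that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
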