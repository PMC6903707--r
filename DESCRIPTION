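Package: mrstrat
Title: Stratified Mendelian Randomization of Body Mass Index on Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratified Mendelian randomization (MR) of body mass
    index (BMI) on type 2 diabetes risk in large biobank-style cohorts.
    Provides a calibrated synthetic-cohort simulator (polygenic risk,
    family history, genotype instruments), per-variant association scans
    with instrument quality control (missingness, exact Hardy-Weinberg
    mid-p), inverse-variance-weighted and MR-Egger estimation with
    heterogeneity and pleiotropy tests, collider-bias guards
    (instrument residualization and decile-matched subsampling),
    nonlinear MR across exposure quantiles (localized average causal
    effects), and closed-form translation of MR odds ratios into
    relative and absolute risk reductions for given amounts of weight
    loss, with confidence-interval propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
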