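Package: melDivergent
Title: Divergent-Pathway Melanoma Subtyping and Mechanistic Circuit Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-layer molecular analysis of divergent cutaneous
    melanoma development. The cohort layer ingests variant and patient tables,
    applies etiopathogenic (nevogenic vs chronic sun damage) and molecular
    subtype (BRAF+/RAS+/NF1+/triple wild type) classification rules, and
    computes prevalence tables with exact and regression-based group
    association statistics. The mechanistic layer simulates per-patient
    in-silico gene knockdowns on normal-tissue expression, propagates signal
    through effector circuits of signalling pathway graphs, tests differential
    circuit activation with empirical-Bayes moderated t-statistics under a
    bootstrap with Fisher p-value combination and fold-change sign
    concordance, and summarises selected circuits against cancer-hallmark
    annotations. A synthetic-data module generates calibrated cohorts,
    log-normal expression, random pathway DAGs and hallmark score tables with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    withr,
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
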