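Package: ctbTMB
Title: ctDNA-Adjusted Blood Tumor Mutational Burden as a Predictive Biomarker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes blood tumor mutational burden (bTMB) from plasma
    somatic variant calls and adjusts it by estimated circulating tumor DNA
    (ctDNA) input mass -- the product of cell-free DNA input mass and mean
    somatic allele fraction -- to remove tumor-burden confounding. Provides
    the full evaluation pipeline for the adjusted score as a predictive
    biomarker in two-arm immunotherapy cohorts: ROC curves with Youden-index
    cutoff selection against durable clinical benefit, paired DeLong AUC
    comparison, Kaplan-Meier and log-rank survival summaries, Cox
    proportional-hazards models with treatment-by-biomarker interaction
    tests, restricted-cubic-spline hazard-ratio curves with nonlinearity
    tests, and nonparametric group comparisons. Includes a synthetic
    randomized two-arm cohort simulator with burden-driven ctDNA shedding
    so that every stage of the pipeline is testable without external
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    splines
Config/testthat/edition: 3
RoxygenNote: 7.3.3
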