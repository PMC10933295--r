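Package: osteomix
Title: Multi-Omics Subtyping and Fracture-Risk Modelling for Osteoporosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for stratifying osteoporosis
    cohorts from matched methylation, metabolite and gut-microbiota profiles.
    Implements deep latent space fusion (DLSF) clustering -- per-modality
    autoencoders with self-expression layers whose coefficient matrices are
    fused into a sample affinity graph and cut by spectral clustering --
    together with cluster evaluation (balance, phenotype associations,
    resampling stability), differential association matrix (DAM) rewiring
    analysis, stemness-like multi-modal signature (M3S) selection, genotype
    quality control with an exact Hardy-Weinberg test, molecular QTL scans,
    logistic-regression risk models with mRMR feature selection, decision
    curves, covariate-adjusted AUC ranking of fracture-risk biomarkers, and
    exhaustive composite-index panel screening. A configurable synthetic
    cohort generator reproduces the statistical structure these analyses
    assume so every stage can be exercised and calibrated without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    pROC,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
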