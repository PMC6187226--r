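Package: polyrisk
Title: Polygenic Risk Scores, Phenome-Wide Scans, and Variance-Decomposition
    Mediation for Endophenotype Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the downstream consequences of aggregate genetic
    risk. Builds polygenic risk scores from GWAS summary statistics with
    significance-ordered LD clumping, region exclusion and p-value threshold
    sweeps; scans the score against clinical, pathological and molecular
    endophenotypes with covariate residualization and Bonferroni family-wise
    control; quantifies how much of the score's effect on an outcome a mediator
    explains via an LMG (Chevan-Sutherland) variance decomposition with a
    permutation null (the PAEM statistic), and searches for minimal conditioning
    sets rendering outcome and score conditionally independent; maps trait and
    SNP architecture through sign-binarized association profiles, Jaccard
    distances, t-SNE embedding and consensus clustering; detects correlated
    omics modules by consensus label propagation and summarizes them per
    individual; and performs cis expression-acetylation (eQTH) mapping with
    Fisher, hypergeometric and binomial region-enrichment statistics. A fully
    parameterized synthetic-cohort generator with a ground-truth ledger makes
    every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
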