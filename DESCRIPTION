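Package: wgpred
Title: Whole-Genome Prediction and SNP Heritability with Weighted Genomic
    Relatedness Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (G-BLUP / GRM kriging)
    and GREML estimation of narrow-sense SNP heritability for complex traits,
    with functional SNP-prioritization weighting of the genomic relatedness
    matrix, covariate-similarity integration, leave-one-out and repeated
    train/test split evaluation with permutation-tested (convex-hull) AUC,
    quality control of PLINK-format genotypes, derivation of asthma-related
    phenotypes including longitudinal lung-function growth patterns, and a
    synthetic cohort generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
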