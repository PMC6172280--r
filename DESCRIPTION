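Package: sumtwas
Title: Summary-Based Multi-Tissue Transcriptome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for transcriptome-wide association studies (TWAS) from
    GWAS summary statistics and reference expression panels. Provides quality
    control and allele harmonization of summary statistics, LD estimation from
    PLINK reference genotypes, REML estimation of cis-SNP heritability of
    expression, penalized training of per-gene SNP weight models with
    cross-validated model selection, the summary-based TWAS association
    statistic with an adaptive permutation test, SNP-level association
    statistics conditional on predicted expression, and Bayesian
    prioritization of causal genes at associated regions via Bayes factors and
    rho-credible gene sets. A synthetic-data module generates genotypes with
    local LD, cis-heritable expression, GWAS summary statistics and correlated
    TWAS Z-score regions so that every stage, including credible-set coverage
    calibration, is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
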