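Package: generank
Title: Gene-Wise Scoring Methods for Detecting Causal Genes from Common
    and Rare Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation pipeline comparing four gene-wise
    scoring methods for the detection of causal genes from mixed
    common/rare variant data: the maximum marginal statistic, Hotelling's
    T2 combination of marginal statistics, the multivariate likelihood
    ratio test, and an L1-penalised (LASSO) regression score. Includes
    indicator-based collapsing of rare nonsynonymous variants into
    gene-level supermarkers, construction of analysis datasets under
    alternative allele-frequency cutoffs, rank-based enrichment
    evaluation of causal genes over simulation replicates, mixed-model
    comparison of analysis scenarios, permutation p-values,
    characterisation of genes on which methods disagree, and synthetic
    generators for a mini-exome study with quantitative and binary
    endpoints and for case-control single-gene power scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
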