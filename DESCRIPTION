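Package: matwas
Title: Multi-Ancestry Transcriptome-Wide Association Analysis with
    Sum-of-Single-Effects eQTL Fine-Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-ancestry transcriptome-wide
    association studies (TWAS): multi-population Bayesian sum-of-single-effects
    cis-eQTL fine-mapping with credible sets and purity filtering,
    population-specific expression weight models (dense and sparse),
    harmonization and conditional imputation of GWAS summary statistics,
    summary-based TWAS association tests with genomic-control calibration,
    sample-size-weighted z-score meta-analysis, Bayesian gene-level
    fine-mapping over causal-gene configurations within LD blocks, and
    cross-population concordance analytics. Includes a synthetic-data
    generator emulating a three-population eQTL reference panel with
    population-specific allele frequencies, linkage disequilibrium, sparse
    cis-regulatory architecture, hidden expression factors, and
    gene-expression-mediated GWAS signal, so that every stage of the pipeline
    is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
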