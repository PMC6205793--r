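Package: methylaCA
Title: Differential Methylation and Immune Cell-Type Signature Analysis
    for Placental Inflammation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for epigenome-wide association studies
    (EWAS) of acute chorioamnionitis (aCA) in placental tissues (chorionic
    villi, chorion, amnion) profiled on Illumina methylation arrays.
    Provides per-CpG covariate-adjusted linear modelling on M values with
    optional empirical-Bayes variance moderation, Benjamini-Hochberg FDR
    control and delta-beta effect sizes; probe filtering and sample QC;
    parametric empirical-Bayes batch adjustment for chip and chip-row
    effects; ancestry inference from AIM-SNP genotypes by classical
    multidimensional scaling; matched-tissue correlation with shuffled
    nulls and DM-set overlap testing against resampling and hypergeometric
    nulls; immune cell-type-specific CpG signature derivation, trend
    concordance against cell references, and hierarchical clustering with
    multiscale-bootstrap cluster stability (AU/BP) and Monte-Carlo split
    significance. A synthetic-cohort generator with full truth tables makes
    every stage testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
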