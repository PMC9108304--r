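Package: clonefire
Title: Clonality, Diversity and Spatial Genetic Structure of Fire-Managed
    Invasive Grasses from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A population-genomic toolkit for asking whether a disturbance
    regime (such as preventative roadside burning) changes genetic structure,
    diversity and the mode of reproduction in partially clonal invasive
    grasses genotyped on reduced-representation SNP platforms (DArTseq-style
    dosage reports). Implements the full desk pipeline: two-stage SNP quality
    filtering with an attrition ledger, PCA / hierarchical-clustering /
    k-means population structure, principal-component and latent-factor
    outlier scans with genomic-inflation calibration, Weir-Cockerham F_ST and
    Mantel isolation-by-distance, rarefied allelic richness and F_IS
    clonality signatures, maximum-likelihood pairwise kinship via an EM fit
    of the three identity-by-descent modes, multi-scale asexuality rates, and
    fire-by-cluster regression models (OLS, cluster-robust OLS, logit-link
    beta regression). A cultivar/clone genotype simulator with known truth
    underpins all testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
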