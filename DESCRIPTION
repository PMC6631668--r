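Package: radpanel
Title: Design and Evaluation of Low-Density SNP Genotyping Panels from
    RAD-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design low-density, genome-evenly-spaced SNP
    genotyping panels from RAD-derived variant data anchored on a linkage
    map, and to evaluate panel performance for population genetics.
    Implements the locus-filtering cascade used for assay (KASP-style)
    panel design (minor allele frequency, per-tag SNP count, edge and
    primer-zone windows, map anchoring), greedy minimum-spacing marker
    selection on a linkage map, seeded down-sampling and fixed-marker
    addition, and a panel-evaluation suite: expected and observed
    heterozygosity, Fis, site-uniqueness and pairwise Fst, allelic
    richness by rarefaction, an Fst-versus-heterozygosity outlier scan,
    Rosenberg's informativeness for assignment with marker-equivalence
    extrapolation, Mantel tests for isolation-by-distance, supervised
    maximum-likelihood admixture classification, and cross-marker
    concordance.  A synthetic-data module generates linkage maps, RAD
    tags, two-lineage genotypes, microsatellite tables and site networks
    with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
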