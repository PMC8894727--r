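Package: bntifeat
Title: Feature-Level Beta Nearest Taxon Index for Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much each individual feature (a microbial taxon or
    an organic-matter molecular formula) contributes to ecological convergence
    or divergence across a set of samples, using a feature-level variant of the
    beta nearest taxon index (betaNTI_feat). Implements the observed
    feature-level beta mean nearest taxon distance, a tip-shuffling null model
    with phylogenetic-noise injection, z-score classification of feature
    contributions in dataset, group, and pairwise modes, whole-community
    betaMNTD/betaNTI and taxonomic dissimilarities, molecular-formula property
    calculation (DBE, modified aromaticity index, NOSC, Kendrick defect) with
    van Krevelen compound classes, a molecular characteristics dendrogram
    (MCD) builder, contribution summaries, a simplified co-contribution
    network-module analysis, and synthetic-data generators for calibration and
    power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
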