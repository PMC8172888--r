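Package: phylofreq
Title: Phylogenetic Comparative Analysis of Acoustic Signal Allometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analyses of acoustic signal frequency
    across species on phylogenies: maximum-likelihood phylogenetic
    generalized least squares (PGLS) with Pagel's lambda, phylogenetic
    signal estimation, AIC-weighted averaging of model output across a
    sample of trees to account for phylogenetic uncertainty, standardized
    slopes and a Z test comparing allometries between signal classes,
    absolute-residual heteroscedasticity regressions, one-way ANOVA
    intraclass-correlation repeatability of repeated acoustic
    measurements, peak-frequency extraction from audio recordings, and a
    synthetic-data generator (Yule trees, branch-length-jittered tree
    samples, lambda-structured traits, noisy repeated measurements) that
    emulates the structure of large cross-species song/call datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
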