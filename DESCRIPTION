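Package: riversed
Title: Abundance-Class Partitioning, Co-Occurrence Networks and Assembly
    Processes for River Sediment Microbiomes
Version: 1.0.0
Authors@R:
    person("Riversed", "Maintainers", email = "riversed@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing amplicon sequence variant (ASV) tables from
    spatially structured sediment bacterial communities: rarefaction and
    Good's coverage, six-way abundance-class partitioning of taxa into
    abundant and rare categories, alpha diversity (Chao1, Shannon, Faith
    phylogenetic diversity) and beta diversity (Bray-Curtis, unweighted
    UniFrac), distance-decay regressions and ANOSIM with permutation
    significance, thresholded Spearman co-occurrence networks with
    Erdos-Renyi null ensembles, degree-distribution fits, keystone and
    observed/random co-existence statistics, betaNTI and Raup-Crick
    (Bray-Curtis) null models with five-way ecological process
    classification, Mantel and partial Mantel tests, variance partitioning
    via redundancy analysis, and a synthetic community generator with
    controllable assembly regimes for ground-truth validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
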