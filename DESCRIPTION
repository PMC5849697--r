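Package: mcfsid
Title: Monte Carlo Feature Selection and Interdependency Discovery for
    Omics Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks features of high-dimensional omics datasets (DNA
    methylation beta-values, gene expression) by their importance for
    predicting dichotomized patient survival, using Monte Carlo Feature
    Selection with Interdependency Discovery (MCFS-ID): thousands of
    decision trees grown on random feature subsets, aggregated into a
    relative-importance ranking with a permutation-based significance
    cutoff and a directed graph of feature interdependencies from
    tree-path co-occurrence. Includes corroborating dependency statistics
    (mutual information, interaction information, Kruskal-Wallis with
    Bonferroni correction, correlation matrices), classifier-based
    validation by stratified cross-validation and train/test evaluation,
    Kaplan-Meier stratification of survival by methylation level with
    log-rank testing, probe-centred methylated-region construction with
    BED-interval intersection, and a synthetic TCGA-like data generator
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    survival,
    rpart,
    class,
    randomForest,
    e1071,
    igraph,
    yaml,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
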