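Package: prstransfer
Title: Simulation and Evaluation of Polygenic Score Transferability Across
    Diverged Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how polygenic risk scores (PRS) generalize
    within and across genetically diverged populations. Simulates structured
    genotype panels under the Balding-Nichols model with founder-haplotype
    linkage disequilibrium, builds quantitative traits of sparse or
    MAF-coupled architecture, runs discovery genome-wide association studies,
    constructs pruning-and-thresholding PRS via greedy LD clumping, and
    evaluates transfer accuracy with incremental adjusted R-squared, bootstrap
    confidence intervals, relative accuracy, loss of accuracy, and the
    Daetwyler expected accuracy. Includes inverse-variance-weighted
    meta-analysis, reference-anchored ancestry assignment from principal
    components, and cross-cohort phenotype comparison tests
    (Kolmogorov-Smirnov, variance-ratio F, clustered correlation matrices,
    Mantel permutation test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    nnet,
    ranger,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
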