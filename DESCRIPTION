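Package: chromclose
Title: Closeness-Measure Profiling of Chromatin Domains and CpG Methylation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the positional influence of chromatin-modification
    domains (histone marks, histone variants, DNA-binding factors called as
    ChIP-seq peak intervals) on single CpG loci through a closeness measure
    (CM) in [0,1], and builds the downstream inference pipeline on top of it:
    assembly of locus-by-feature CM profiles with binary genomic-element
    indicators, multiple linear regression of methylation on the profile with
    t-test feature selection, 10-fold cross-validation and permutation
    empirical p-values, homogeneity-based clustering of loci into chromatin
    modules with value-swap randomization controls, equal-frequency
    binarization and score-based Bayesian-network structure learning with
    compelled/reversible edge identification, interaction tallying across
    module networks, network topology metrics against edge-count-matched
    random graphs, and partial-correlation validation of discovered pairs on
    independent signal matrices. A synthetic-data module generates domains,
    loci, planted linear methylation models and planted dependencies so every
    stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
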