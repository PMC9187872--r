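Package: chirptools
Title: Dual-Probe ChIRP-seq Consensus Binding Sites and RNA-Interactome
    Enrichment Statistics
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for chromatin isolation by RNA purification
    (ChIRP-seq) experiments performed with split "even" and "odd" probe
    sets in biological triplicate: per-base take-lower merging of probe-set
    coverage tracks, a simplified Poisson peak caller, dual-probe and
    triplicate consensus rules, removal of direct probe-capture artifacts
    via exact motif-match p-values (score-distribution dynamic
    programming), genomic annotation of consensus sites, and integration
    with knockdown expression data (differential-expression status,
    two-cluster structure, per-day lncRNA-target correlation). A companion
    module implements SAM/Perseus-style label-free proteomics enrichment
    statistics (down-shifted Gaussian imputation, s0-moderated t tests,
    permutation-based FDR) for RNA affinity-purification experiments.
    Seeded generators simulate every input so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
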