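Package: ReporterScreen
Title: Analysis of FACS-Sorted CRISPR-Cas9 Transcriptional Reporter Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of pooled CRISPR-Cas9 loss-of-function
    screens read out by fluorescent transcriptional reporters and FACS
    sorting of low- and high-expressing tails. Provides a statistically
    explicit simulator of sorted-bin screens, construction of the
    staggered amplicon reference and mismatch-tolerant sgRNA counting
    with index demultiplexing, alpha-robust-rank-aggregation (alpha-RRA)
    gene scoring against a non-targeting-control empirical null with
    permutation p-values, hit filters for the centromere-proximal
    reporter-loss artifact and transcriptionally inactive genes,
    assembly of directed activator/repressor regulatory networks, and
    cross-screen co-regulation analyses including shared-regulator
    overlap matrices and two-group screen clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, PooledScreens, Software, GeneRegulation, NetworkInference
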