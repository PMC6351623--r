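Package: intronr
Title: Differential Intron Retention Analysis for Yeast RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from annotated RNA-Seq alignments and
    tests for differential retention between mutant and control strains.
    Derives an intron-only feature set from a gene annotation, counts reads
    with intersection-strict semantics, filters low-expression features on
    reads per kilobase, and fits per-feature negative-binomial Wald tests
    with median-of-ratios size factors that can be borrowed from the
    complete gene-level dataset when testing the small intron sub-matrix.
    Includes correspondence-analysis library clustering, fold-change
    heatmap ordering, a synthetic-data generator with ground truth for the
    five-strain three-replicate design, Dollo parsimony mapping of gene
    losses on a species tree, and Pfaffl relative quantification of qPCR
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1),
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    ape
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    phangorn,
    MASS,
    jsonlite
Config/testthat/edition: 3
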