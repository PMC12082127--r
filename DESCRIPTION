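Package: lrtriage
Title: Multi-Caller Variant Triage and Concordance for Long-Read Clinical
    Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates the outputs of a multi-caller long-read variant
    calling pipeline for clinical review. Provides per-caller call routing
    with size bridging between the small-variant and structural-variant
    callers, a structured filtering cascade for structural variants and
    read-depth copy-number segments (caller restriction, chromosome
    partition, mechanistic gene-impact classification, phenotype-gene
    intersection, declarative logic rules, cross-caller merging), tandem
    repeat genotyping from spanning reads with motif-run decomposition and
    locus-specific pathogenicity rules, and truth-set concordance
    statistics (exact matching, stratified sensitivity with Wilson score
    intervals, weighted aggregate sensitivity). A deterministic synthetic
    fixture generator emulates truth sets, per-caller VCF dialects with
    configurable detection profiles, exon BED panels and repeat-spanning
    reads so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: StructuralVariation, CopyNumberVariation, VariantDetection,
    Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
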