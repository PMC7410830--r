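Package: devdecomp
Title: Decomposing Developmental Transcriptomes and Epigenomes into
    Cell-Type-Resolved Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for structuring a multi-tissue
    developmental transcriptome and for decomposing whole-tissue epigenomic
    state maps into cell-type-resolved candidate cis-regulatory elements
    (cCREs) using single-cell RNA-seq marker genes. Provides bulk RNA-seq
    structuring (dynamic/ubiquitous gene partition, PCA with z-scored
    sample scores, hierarchical clustering with major-clade extraction,
    canonical correlation analysis against sample metadata, embryo sex
    inference), single-cell QC, normalization, dispersion-based
    tight-cluster feature selection and one-vs-rest Wilcoxon marker
    calling with exclusive-marker derivation, negative-binomial
    signal-to-P-value track conversion with 20-kb local background
    adjustment, DHS peak merging with chromatin-state whitelist filtering
    and nearest-expressed-TSS assignment, promoter motif enrichment with
    dual-annotation significance and bipartite motif-cluster graphs, and
    seeded synthetic-data generators with ground-truth tables for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
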