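Package: kinomer
Title: Plant Kinome Identification, Duplication and Coexpression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies typical protein kinases from profile-HMM domain-hit
    tables, classifies them into kinase groups and subfamilies, merges kinomes
    called on two genome assemblies into a non-redundant set with greedy
    identity clustering, detects tandem and segmental gene duplications,
    associates kinase genes with nearby transposable elements, aggregates
    transcript quantifications (TPM) to subfamily level, and builds
    control-versus-stress subfamily coexpression networks with Kleinberg hub
    scores and edge betweenness. A seeded synthetic-data module generates
    genomes, annotations, transposable elements and expression matrices with
    planted ground truth so every pipeline stage can be validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    pheatmap,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
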