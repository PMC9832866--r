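Package: TOGCNet
Title: Comparative Time-Ordered Gene Co-Expression Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and cross-species comparison of time-ordered gene
    co-expression networks (TO-GCNs) from replicated time-course RNA-seq.
    Provides TPM normalization, a pairwise time-point differential-expression
    filter, seed-rooted breadth-first level assignment of transcription-factor
    networks thresholded on Pearson correlation, decomposition of two species'
    networks into consensus and species-specific components over an ortholog
    map, stage-resolved pathway subnetwork extraction, hub-gene calling,
    hierarchical regulator-chain resolution, and confirmation of
    regulator-target edges by position-weight-matrix scanning of upstream
    sequences with exact p-values. A synthetic-data module generates
    two-species time-course datasets with a fully known planted regulatory
    cascade so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
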