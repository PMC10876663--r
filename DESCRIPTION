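Package: hypoTF
Title: Transcription-Factor Prioritization from Hypomethylated Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate master-regulator transcription factors from
    tumor-specific hypomethylated regions (hypoDMRs). Calls region-level
    hypoDMRs from beta values, scores position-weight-matrix motif enrichment
    in hypoDMRs against background regions, infers TF target genes as nearest
    genes of motif-bearing hypoDMRs with open chromatin, ranks TFs by
    preranked gene set enrichment (GSEA) of their targets in a tumor-versus-
    normal expression ranking, builds TF-activity gene signatures from
    consensus ChIP-seq peaks intersected with knockdown-downregulated genes,
    scores samples by signature expression, and screens pathway gene sets
    between expression-stratified sample groups. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
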