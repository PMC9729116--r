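Package: dmgatlas
Title: Multimodal Dissection of Diffuse Midline Glioma Cell States, Regulatory
    Elements and Spatial Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for H3-K27M diffuse midline glioma single-cell
    multi-omics: quality control and transforms for single-cell TPM expression,
    per-sample NMF program derivation with consensus merging into metaprograms
    and score-threshold cell-state assignment, snATAC-seq processing (QC,
    TF-IDF/LSI, gene activity scores), cross-modality CCA matching and
    100-cell pseudobulk construction, correlation-based linking of candidate
    cis-regulatory elements to their nearest genes with identification of
    genes with predictive chromatin, integrative transcription-factor circuit
    selection, and permutation-based spatial neighborhood analysis of in situ
    cell maps. Ships a synthetic-data generator that plants known cell-state
    signatures, peak-gene links, motif enrichments and spatial niches so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
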