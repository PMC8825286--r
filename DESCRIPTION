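Package: regscape
Title: Multimodal Regulatory Landscape Analysis for Single-Cell and 3D Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the regulatory landscape of a differentiating
    tissue from paired single-cell RNA and ATAC data together with cell-type
    resolved Hi-C contacts, CpG methylation and massively parallel reporter
    assays (MPRA). Implements correlation-based enhancer-gene pair linkage
    against a trans-chromosomal null, pseudotime-offset (dPD) classification of
    enhancer priming, Hi-C insulation and TAD boundary calling, A/B compartment
    assignment and compartment strength, a bounded k-nearest-neighbour contact
    enrichment score, aggregate TAD and pair (APA) enrichment, permutation
    statistics for transcription-factor motif looping and methylation
    specificity, bisulfite conversion QC, methylation metaprofiles, MPRA
    library design with scrambled and motif-mutant controls and robust (MAD-z)
    activity scoring. A synthetic-data generator with planted ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    mgcv,
    jsonlite,
    Rcpp,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
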