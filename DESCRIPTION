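Package: tagtrace
Title: Extraction, Error Correction and Quantification of Synthetic Cellular Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for extracting synthetic DNA barcodes (lineage-tracing
    tags, Pro-codes, sgRNAs) from bulk DNA, single-cell and spatial sequencing reads.
    Supports reference-based matching (exact multi-pattern search, edit-tolerant
    semi-global alignment) and reference-free extraction from flanking regions, masked
    patterns and length intervals. Sequencing errors are corrected with a two-stage
    algorithm: pigeonhole n-gram fingerprint pre-clustering followed by count-ordered
    forest refinement, applied globally across samples with per-sample count correction.
    Includes UMI dominant-barcode collapsing, whitelist and quality filtering, count
    matrix output (CSV and H5AD), clone assignment from combinatorial tag sets, and a
    ground-truthed amplicon read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Optional Python (>= 3.8) with the anndata package for H5AD export.
Config/testthat/edition: 3
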