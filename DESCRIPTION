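Package: paneldx
Title: Targeted Gene-Panel Sequencing Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested toolkit for capture-based gene-panel diagnostic
    sequencing: FASTQ read quality filtering (adapter pollution, ambiguous
    bases, low quality), per-region coverage statistics, detection of large
    exon deletions and duplications from normalized read-depth z-scores,
    rule-based variant filtering and four-tier pathogenicity triage for a
    candidate-gene panel, and confusion-matrix benchmarking of SNV calls
    against a truth set. Ships a synthetic fixture generator that emulates
    correlated capture depths, implanted copy-number events and annotated
    variant cohorts so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
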