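Package: cooccupy
Title: Transcription Factor Co-Occupancy Analysis at Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative ChIP-seq/RNA-seq toolkit for establishing
    transcription-factor co-occupancy at cis-regulatory modules.  Provides
    peak ingestion and nearest-TSS annotation, position-weight-matrix
    scanning of summit windows with a relative-score threshold, a
    dinucleotide-preserving shuffle null with Fisher enrichment tests,
    motif co-occurrence classification (Sox-only, Tcf-only, both),
    differential-expression filtering and spatial-enrichment classing,
    hypergeometric gene-set intersection, four-way regulatory
    categorization, summit-centered coverage matrices, and a synthetic
    data generator with a ground-truth manifest so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
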