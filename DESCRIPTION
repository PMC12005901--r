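Package: cnvbench
Title: Exon-Overlap Benchmarking of Germline CNV Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clinically oriented benchmarking of germline copy-number
    variant (CNV) call sets from short-read whole-genome sequencing.
    Classifies deletion and duplication calls against a truth set by
    shared overlap of splice-padded coding exons with dosage-direction
    matching, converts insertion-represented truth duplications into DUP
    records by flank identity, spikes synthetic gene models into
    high-confidence regions to increase the number of scoreable exon
    overlaps, computes GA4GH-style sensitivity and precision stratified
    by event type, length and exons spanned, and implements a multi-rule
    recurrent-artifact filter (size window, junction-only long calls,
    assembly-gap overlap, reciprocal overlap with a recurrent-artifact
    blacklist) together with a blacklist builder that discovers
    recurrent artifacts across samples. A seeded fixture generator
    produces fully synthetic references, gene models, truth sets and
    call sets with known composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
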