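Package: tssbreadth
Title: H3K4me3 Breadth Patterns at Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of H3K4me3 ChIP-seq peak breadth around
    transcription start sites (TSS) and its association with differential
    gene transcription. Converts strand-aware read placements into binned,
    input-normalized TSS profile matrices on a log2-versus-background scale,
    classifies TSSs into four breadth patterns (narrow peak, upstream
    extended, downstream extended, broad symmetric) with two-component
    Gaussian mixtures fit by EM, and quantifies the association of breadth
    and breadth change with transcription: expression level and variance by
    pattern, Fisher odds ratios against differential expression,
    region-specific dose-response of transcription on H3K4me3 change,
    gene-set overrepresentation, and promoter motif positional enrichment.
    Includes a synthetic-data generator that emulates the assumed data
    structure so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    withr
Config/testthat/edition: 3
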