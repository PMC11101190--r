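Package: protoscan
Title: Detection of Proto-Genes from Mutation-Aware Window Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting proto-genes, previously silent genomic
    regions that gain transcription after new mutations, in an evolving
    bacterial lineage. The package partitions an ancestral genome into
    fixed-width strand-aware windows, applies GenomeDiff-style mutations to
    obtain each evolved clone's sequence together with an exact coordinate
    liftover, counts strand-aware read evidence with nonunique-all
    semantics, normalises to NRC/TPM, performs negative-binomial Wald tests
    for differential transcription and an interaction test for differential
    translation, and runs a filter cascade over mutation-downstream
    candidate regions (overlap filters, ancestral-silence screen,
    cross-condition screen, cause classification, ORF scan). A synthetic
    data generator with planted proto-gene events provides ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
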