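Package: quantnet
Title: Reference-Based Evaluation of De Novo Transcriptome Assembly and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates de novo transcriptome assemblies against reference
    transcripts without re-running aligners or quantifiers. Merges local
    BLAST alignments (HSPs) into global transcript-contig alignments with
    recovery, accuracy and alignment-score statistics; builds sequence
    ambiguity networks (connected components of near-identical sequences)
    over contigs and transcripts; classifies contigs as full-length,
    incomplete, over-extended, family-collapse or duplicated; and scores
    quantification reliability via ground-truth TPM, relative error, read
    proportion of estimated abundance (RPEA) and component-level
    aggregation. Includes a synthetic fixture generator that plants each
    error category with known provenance so the whole pipeline is testable
    without external aligners or quantifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
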