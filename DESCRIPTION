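Package: gvfkit
Title: Genome Variation Format Toolkit with Sequence Ontology Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, write and validate Genome Variation Format (GVF) variant
    annotation files, reason over the Sequence Ontology (SO) is_a graph, call
    SO consequence terms (missense, splice, frameshift, UTR, ablation, ...)
    for sequence alterations against reference gene models, and run
    ontology-aware subsumption queries and dataset cross-tabulations. Ships a
    pinned SO subset covering the sequence_variant and sequence_alteration
    branches, the 34-term Ensembl consequence vocabulary, and a deterministic
    synthetic-fixture generator that plants variants whose consequence is
    known by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
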