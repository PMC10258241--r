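Package: dexskip
Title: Domain-Oriented Exon Skipping Target Selection and Splice-Modulating
    Oligonucleotide Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds in-frame combinations of one or more consecutive exons
    whose removal cleanly deletes a whole protein domain from a coding
    transcript, ranks the resulting skip candidates by pathogenic
    loss-of-function variant burden and estimated population reach, designs
    candidate splice-modulating antisense oligonucleotides (with
    four-mismatch non-binding controls) against the target exons, and
    predicts the RT-PCR/minigene splice-assay band patterns expected for
    each skip isoform. Includes a deterministic synthetic-gene generator
    with repetitive domain architecture so the whole pipeline is testable
    without external annotation downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
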