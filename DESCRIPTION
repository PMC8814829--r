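Package: exomir
Title: Exosomal Versus Whole-Milk Small RNA-Seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA-seq workflow for comparing microRNA
    content of milk exosomes against whole milk: read cleaning with
    explicit low-complexity composition filters and contaminant ncRNA
    subtraction, mature-miRNA quantification on pre-miRNA hairpins using a
    positional counting window, differential abundance via a conditional
    negative-binomial exact test with two-tier fold-change classification,
    genomic clustering of pre-miRNAs and seed-based family assignment, and
    miRNA target prediction in 3' UTRs by seed matching with
    nearest-neighbor duplex free-energy scoring. Includes a synthetic-data
    generator that writes two-condition replicate FASTQ libraries with
    known ground truth so every stage is testable without external data.
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
    rtracklayer,
    jsonlite,
    stringi,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
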