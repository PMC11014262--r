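Package: mircurate
Title: Stringent microRNA Discovery and Curation from Small RNA-Seq in
    AT-Rich Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for annotating bona fide microRNAs from
    small RNA sequencing data in non-model, AT-rich genomes. Implements
    adapter trimming and 18-35 nt length selection, exhaustive ungapped
    genome alignment with at most one mismatch, fractional placement of
    multimapping reads, read clustering, minimum-free-energy hairpin
    folding at a configurable temperature, read-evidence miRNA duplex
    calling with 5' processing-precision statistics and duplex geometry
    (mismatches, bulges, 2-nt 3' overhangs), a configurable
    two-out-of-three criteria-set verdict, structured-ncRNA and
    transposon exclusion, genomic-context classification, exact-duplex
    paralog search, cross-genome homolog search with compensatory
    substitution classification, synteny-block merging, and
    characterization statistics. Includes a synthetic-data generator
    that plants miRNA, siRNA and structured-ncRNA decoy loci in an
    AT-rich genome and simulates replicate read libraries with a
    machine-readable truth table, so that every stage is verifiable by
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
SystemRequirements: ViennaRNA (RNAfold on the PATH)
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
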