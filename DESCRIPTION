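Package: dogscan
Title: Discovery and Quantification of Downstream-of-Gene (DoG) Readthrough
    Transcripts from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies transcriptional readthrough regions
    (DoGs, Downstream-of-Gene transcripts) from genome-mapped RNA-seq
    alignments.  Builds a most-inclusive gene-loci annotation from one or
    more GTF files, infers library strandedness natively, downsamples
    samples to a common depth for comparable discovery, detects regions of
    continuous non-genic read coverage downstream of gene 3' ends and
    elongates them in overlapping windows, combines DoG sets across samples
    by union or intersection, and reports DoG expression as RPKM.  Includes
    a seeded synthetic-read simulator with planted readthrough ground truth
    for end-to-end validation.
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
    GenomeInfoDb,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
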