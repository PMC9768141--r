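Package: readthroughr
Title: Detection and Characterization of Readthrough (Polycistronic) Transcripts from Long-Read Isoforms
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls readthrough-transcript (RT) loci from full-length transcript
    models against a gene annotation, classifies intergenic splicing (IS) and
    first-gene polyadenylation behavior, scans polyadenylation-signal (NUE) and
    cleavage-element (CE) hexamer windows upstream of polyadenylation sites,
    computes ribosome-profiling translation efficiency of first versus second
    open reading frames, and tests enrichment of organelle-targeted first
    genes. Ships a seeded synthetic-data generator that emits genome FASTA,
    GFF3 annotation, BED12 transcript models, CAGE TSV, ORF count tables and
    localization tables with planted ground truth for every pipeline stage,
    plus an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
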