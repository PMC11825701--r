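Package: isoforge
Title: Structural Classification, ORF Consequence Calling and Event
    Quantification for Long-Read Transcript Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for building a full-length transcriptome atlas from
    long-read transcript models: SQANTI-style structural classification
    against a reference annotation (FSM/ISM/NIC/NNC and friends),
    detection of intron-derived cassette ("cryptic") exons, transcript
    5'/3' end validation against CAGE peaks and polyA motifs, ORF
    prediction with NMD feature calling and a five-class ORF-consequence
    scheme, isoform abundance and diversity summaries with depth
    saturation curves, cohort-level quantification of cassette-exon
    inclusion from STAR splice-junction tables, and scanning for
    ESRP-type UGG-rich intronic motifs.  A deterministic synthetic-data
    generator produces genomes, annotations, labelled isoform events and
    junction counts at known inclusion levels so that every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    minpack.lm,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
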