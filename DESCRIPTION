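Package: besmap
Title: BAC-End Sequence Mapping, Physical Map Contigs, Rearrangement
    Detection and Polymorphism Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of BAC-end sequences (BESs) against a
    reference genome. Provides a synthetic-data generator for reference and
    derived cultivar genome pairs with planted polymorphisms and
    rearrangements plus a simulated BAC clone library; a seed-and-extend
    local aligner with Karlin-Altschul E-values and a BLAST-style tabular
    hit format; paired-end placement under explicit uniqueness, identity,
    coverage and distance criteria; hypothetical BAC contig construction
    with euchromatin/heterochromatin coverage tables; clustering of
    discordant clone pairs into candidate inversion and translocation
    events; and SNP/indel calling from alignments with
    transition/transversion and genic classification, polymorphism density
    tables and VCF output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
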