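Package: rdnaunit
Title: Recovery, Annotation and Repeat Analysis of Ribosomal DNA Repeat Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and annotating the tandemly repeated
    ribosomal RNA gene cluster (rDNA repeat unit) of birds and other
    vertebrates from mixed long- and short-read sequencing data. Provides
    k-mer containment classification to recover rDNA-bearing reads from a
    whole-genome read pool, pileup-majority consensus polishing of gene
    regions, reference-guided transfer of gene and spacer boundaries,
    coverage-based transcription start site calling, detection of the RNA
    polymerase I promoter and of the poly-T plus inverted-repeat
    transcription terminator, and the compositional and repeat statistics
    used to characterise intergenic spacers: GC content, CpG islands
    (Gardiner-Garden and Frommer criterion), perfect microsatellites,
    dispersed motif and complement repeats, polypurine/polypyrimidine
    bendable tracts and G-quadruplex motifs. A synthetic-data generator
    with planted ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
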