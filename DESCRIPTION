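Package: ngskit
Title: Indexed File Access, Relational Tables, Coverage and Wavelet
    Peak Calling for Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A compact toolkit for next-generation sequencing analysis:
    random access by line number to large text, TSV, FASTA and FASTQ
    files through persistent byte-offset indexes; a schema-typed
    relational Table with filtering, stable sorting, bound searches and
    inner/outer joins; strand-aware genomic interval algebra; strand-
    specific per-base coverage with mismatch counting from SAM
    alignments; genomic-interval annotation and per-feature read
    counting with RPKM normalization; and a multiscale continuous-
    wavelet-transform peak caller that ranks candidate ChIP-seq peaks
    by ridge-line persistence across scales. Deterministic synthetic
    genomes, alignments and coverage tracks are included so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
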