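Package: shufflekit
Title: Simulation and Decoding of Recombinase-Driven Genome Shuffling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for barcoded shuffle-cassette experiments in which
    site-specific recombinases (Cre at loxPsym, Bxb1 at attB/attP) induce
    structural variants between transposon-delivered cassettes. Provides a
    sequence-level model of cassettes and the recombination product algebra,
    a seeded simulator of synthetic diploid genomes, clone populations,
    rearrangements and all three sequencing readouts (IVT-seq, amplicon-seq,
    single-cell T7 capture), plus the decoding pipelines: haplotype-resolved
    insertion-site mapping, barcode-pair structural-variant calling with
    scar/ecDNA and translocation subclassification, single-cell clonotype
    reconstruction and genotyping, and gene-dosage expression impact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
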