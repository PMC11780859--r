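Package: ligbias
Title: Ligation Sequence Bias, Ligase Kinetics and Strand-Biased Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing single-stranded DNA ligases from sequencing
    assays. Quantifies positional nucleotide enrichment and the degree-of-bias (DB)
    statistic from randomized-insert (N40) ligation assays, simulates the
    three-reaction ligase mechanism (self-adenylation, adenylyl transfer, ligation)
    as a deterministic mass-action model, maps strand-biased read depth of
    lagging-strand fragments to call replication-origin transitions, and profiles
    GC-content-dependent coverage bias. A synthetic-data module generates
    bias-assay FASTQ reads under a terminal-nucleotide ligation-weight model with
    pool depletion, and strand-switching BED reads around planted origins, so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    deSolve,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
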