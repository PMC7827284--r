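Package: sbdriver
Title: Driver Gene Discovery for Sleeping Beauty Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Sleeping Beauty (SB) transposon
    gene-trap mutagenesis screens. Builds a TA-dinucleotide site index
    from a reference genome, ingests per-tumor SB insertion profiles
    (SBCapSeq-style junction read counts), infers and removes the donor
    concatemer chromosome, collapses insertions to per-gene maximum read
    depth, and classifies candidate tumor suppressor driver genes by an
    exact Poisson-binomial recurrence test under a TA-content null with
    Benjamini-Hochberg (discovery), Holm (genome-significant progression)
    and read-depth-filtered Holm (trunk) tiers. Includes activating
    insertion pattern detection, curated tumor-suppressor list overlap
    statistics (Yates chi-square), oncoprint matrix export, cohort
    summaries, and a fully parameterized synthetic cohort generator with
    local-hopping donor dynamics and junction read simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
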