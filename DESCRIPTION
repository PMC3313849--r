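Package: CpGscout
Title: CpG Island Prediction by Sliding-Window Scanning and Complementary
    Swarm and Genetic Search
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@cpgscout.org",
           role = c("aut", "cre"))
Description: Locates CpG islands in DNA sequences. Provides constant-time
    interval composition statistics (GC content and the CpG
    observed/expected ratio) backed by prefix sums, a sliding-window island
    extractor with window-wise extension, single-base trimming and gap
    merging, stochastic island discovery by particle swarm optimization and
    a genetic algorithm extended with a complementary restart that reflects
    stagnant candidates across the search bounds to escape local optima,
    nucleotide-level prediction evaluation (sensitivity, specificity,
    accuracy, Matthews correlation), a seeded synthetic-genome generator
    with planted islands for calibration and testing, and a command-line
    interface reading FASTA and writing BED6, GFF3 and bedGraph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
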