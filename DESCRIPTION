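Package: tierscan
Title: Tiered Scanning and Cooperation Analysis of Androgen Response Elements
Version: 0.1.0
Authors@R:
    person("Jordan", "Mercer", email = "jmercer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genome-scale analysis of the androgen response
    element (ARE), the palindromic dihexamer AGAACAnnnTGTTCT bound by the
    androgen receptor dimer. Provides position-specific scoring matrix
    construction from consensus strings or aligned binding sites, exact
    p-value motif scanning under a zero-order background via dynamic
    programming over discretized log-odds scores, five-tier degeneracy
    classification of full-site and half-site AREs, annotation of sites
    against gene models into promoter/genic/intergenic categories,
    spaced-motif co-occurrence analysis for cooperating transcription
    factors, region-density and tier hit-rate statistics, and a seeded
    synthetic-data generator with planted sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
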