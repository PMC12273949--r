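Package: madfe
Title: Mutation-Accumulation Spectra and Distributions of Fitness Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of microbial mutation-accumulation (MA) experiments:
    filtering and classification of called variants, mutation spectra and
    biases with confidence intervals, per-bp mutation rates, Poisson
    goodness-of-fit diagnostics, maximum-growth-rate estimation from
    plate-reader OD600 time series, construction of distributions of fitness
    effects (DFEs) with a colony-bottleneck selection-bias correction,
    genome-wide beneficial mutation supply and deleterious load, and a
    synthetic MA-experiment generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
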