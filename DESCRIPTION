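Package: cphmm
Title: Detection of CpG-CpH Differentially Methylated Regions with a
    Three-State Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genomic regions in which CpG and non-CpG
    (CpH) methylation are differentially correlated from whole-genome
    bisulfite sequencing count data. Provides methylation calling with
    bisulfite non-conversion correction (threshold calls for CpGs, exact
    binomial tests with empirical false-discovery-rate calibration for
    CpHs), a three-state hidden Markov model over 180-bp genomic bins that
    segments the genome into positively correlated, negatively correlated
    (CpG-CpH DMR), and uncorrelated states via Baum-Welch transition
    training and Viterbi decoding, downstream hyper-/hypo-mCpH DMR
    classification and annotation overlap, methylation proximity profiles
    around methylated CpGs, and a synthetic-methylome simulator with
    precision/recall benchmarking of the segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
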