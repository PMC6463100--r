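Package: varscreen
Title: Multi-Stage Filtering, Homopolymer Indel Screening and Ensemble
    Merging for Amplicon Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream processing for targeted amplicon sequencing
    variant calls produced by several aligner and caller combinations.
    Implements a three-stage filter cascade (target-region filter,
    caller-style quality-expression filters with a union-retention rule,
    and a trained homopolymer indel filter based on the per-site variance
    and modal frequency of indel event lengths), ensemble merging of
    callsets with a per-variant confidence score, per-amplicon coverage
    and benchmark metrics (sensitivity, specificity), and deterministic
    synthetic-data generators for reads, callsets and labeled training
    indels. All user-facing functions take and return data frames so
    stages compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    Rsamtools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
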