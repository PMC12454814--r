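Package: tailshift
Title: Alternative Polyadenylation, Poly(A) Tail Length and m6A Analysis
    for Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-transcriptional analysis of per-read features derived
    from nanopore direct RNA sequencing: clustering of read 3' ends into
    poly(A) sites, proximal/distal alternative-polyadenylation statistics
    with relative expression difference (RED) scores, Mann-Whitney testing
    of per-transcript poly(A) tail length differences, per-site m6A
    stoichiometry with Fisher-exact differential methylation, metagene
    profiling, TPM quantification and stratified integration analyses.
    Includes a seeded synthetic per-read data generator with planted,
    recorded effects so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
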