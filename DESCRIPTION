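Package: haracne
Title: Higher-Order Data Processing Inequality Pruning for Regulatory
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse engineering of transcriptional regulatory networks
    from gene expression profiles. Builds mutual-information relevance
    networks restricted to transcription-factor-containing gene pairs
    (adaptive-partitioning estimator with a permutation-calibrated
    significance threshold), then removes indirect interactions by
    sequential first- and higher-order data processing inequality (DPI)
    pruning: an edge is dropped when a surviving chain of stronger edges
    through transcription-factor intermediaries explains it. Includes
    bootstrap consensus networks, regulon validation statistics against
    gold-standard gene sets (gain arithmetic, Fisher and hypergeometric
    tests), and a seeded synthetic regulatory-cascade simulator with
    recovery scoring so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
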