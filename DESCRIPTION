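Package: dendrosched
Title: Optimal Parallel Scheduling and Simulation of Dendritic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compartmental simulation of branched neurons with a provably
    optimal parallel schedule for the Hines tree solver. Implements dendritic
    hierarchical scheduling (DHS), which at every step eliminates the k deepest
    processable compartments of the dependency tree, together with an
    exhaustive minimum-step oracle, simulated-parallel execution with
    warp grouping and memory-layout permutation, SWC morphology handling with
    explicit dendritic spines or F_spine membrane scaling, passive cable
    dynamics with AMPA/NMDA synapses and Poisson background noise,
    spine-excitability protocols, and a three-layer dendritic network trained
    with a transfer-resistance gradient rule.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
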