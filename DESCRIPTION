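Package: paretomcts
Title: Multi-Objective Pareto Monte Carlo Tree Search for Target-Aware
    Molecule Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pluggable-policy, pluggable-objective Pareto Monte Carlo Tree
    Search engine for autoregressive, token-by-token molecule generation
    conditioned on one or more protein targets. The search maintains a global
    pool of mutually non-dominated molecules, scores candidate tokens with a
    vectorial ParetoPUCT selection criterion, fuses next-token distributions
    from several target-conditioned policies by mean pooling for multi-target
    design, and evaluates generated molecules with standard drug-likeness
    descriptors (QED, synthetic accessibility, natural-product likeness,
    Crippen LogP) plus an optional external docking adapter. Ships an
    enumerable toy sequence MDP with brute-force oracles so every search
    component is testable without model weights or chemistry binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
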