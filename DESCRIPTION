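Package: fuzzynet
Title: Fuzzy-Logic Continuous Regulatory Network Simulation of CD4+ T-Cell
    Differentiation
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles Boolean interaction rules into continuous fuzzy-logic
    ordinary differential equations and integrates them under configurable
    cytokine, nutrient and oxygen microenvironments. Node propositions are
    evaluated with the multiplicative t-norm, gated through a sigmoid
    characteristic function, and relaxed with first-order decay; attractors
    are classified as fixed points or limit cycles. Ships a reconstructed
    68-node model of early CD4+ T helper cell activation and differentiation
    (Th1, Th2, Th17, Treg and T follicular helper lineages, including hybrid
    and oscillatory regimes) together with scenario presets, phenotype
    classification, and bisection scans that locate critical input levels at
    which polarization switches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
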