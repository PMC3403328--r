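Package: pbnred
Title: State Reduction and Minimax Control of Probabilistic Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building, reducing and controlling probabilistic
    Boolean network (PBN) models of gene regulation. Assembles the
    column-stochastic state transition matrix of a PBN with external control
    nodes, adds the Kronecker-product random gene perturbation model, and
    applies a transition-probability-based state reduction that iteratively
    deletes states whose inflow falls at or below the perturbation threshold
    while preserving attractors and the initial state. Solves the
    finite-horizon minimax (worst-case terminal cost) optimal control problem
    by backward dynamic programming on either the original or the reduced
    state space, with independent brute-force oracles, and enumerates the
    in-degree-one Boolean network ensemble to study the distribution of
    unreachable states. Includes a seeded random PBN generator, experiment
    runners, JSON and MatrixMarket input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
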