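Package: sispart
Title: Partitioned Event-Driven Simulation of SIS Epidemics on Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Event-driven simulation of Markovian
    susceptible-infected-susceptible (SIS) epidemics on fixed undirected
    graphs, with a partitioned engine in which per-part event-driven
    simulators advance in synchronized epochs and exchange either a border
    infection summary statistic or full border states (ghost-cell mode)
    over capacity-one channels. Includes the exact sequential
    next-reaction baseline, time-driven baselines (rejection sampling and
    the exact per-epoch transition matrix), quenched mean-field theory
    (master equation, discrete epoch map, spectral epidemic threshold,
    fixed points), synthetic graph generators (Erdos-Renyi, stochastic
    block model), uniform and block partitions, border tables, message
    accounting, and a replication harness for repeated runs, trajectory
    averaging and divergence analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
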