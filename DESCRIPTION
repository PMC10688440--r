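Package: potionsim
Title: Agent-Based Simulation of Cumulative Innovation on Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Potions Task, an agent-based model of cumulative,
    recombinatorial innovation on social networks. Pairs of agents combine
    triads of items from their inventories to discover higher-tier items along
    two path-dependent trajectories, culminating in a crossover innovation that
    requires uniting both trajectories. The package provides generators for
    Erdos-Renyi, ring and connected caveman networks, a loader for weighted and
    unweighted edge lists, a fast compiled simulation engine with a pure-R
    reference implementation, inequality measures (Gini coefficient and
    variants) and centrality reports for first discoverers, plus a batch
    experiment runner with deterministic replicate seeding.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
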