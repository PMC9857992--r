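Package: wormnet
Title: Structural Metrics and Growth Models for Developing Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing directed chemical-synapse networks across
    development and for simulating their growth. Reads raw synapse tables and
    collapses them to simple directed graphs; computes density, mean degree,
    average shortest path length, clustering, in/out degree distributions, the
    per-node in/out-degree asymmetry index and the small-world coefficient
    against Erdos-Renyi and degree-preserving null ensembles; and implements a
    network-evolution model in which edges are added by preferential attachment
    with separate initial attractiveness for in-degrees and out-degrees and
    removed uniformly at random, together with its continuum-theory rate
    equation. Includes seeded simulation experiments (asymmetry sweeps, degree
    distribution regimes, connectome matching) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    deSolve,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
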