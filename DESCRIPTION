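Package: dcjmedian
Title: DCJ Genome Medians and Gene-Order Phylogenies by Discrete
    Quantum-Behaved Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ancestral genome inference from signed gene orders
    under the double-cut-and-join (DCJ) model.  Provides the adjacency-graph
    DCJ distance, enumeration and sampling of optimal DCJ sorting steps, a
    discrete quantum-behaved particle-swarm median solver that searches for
    a genome minimizing the summed DCJ distance to three given genomes, a
    seeded inversion/transposition rearrangement simulator, GRAPPA-style
    iterative tree scoring with circular-ordering lower-bound pruning, and
    evaluation metrics (adjacency accuracy, Robinson-Foulds error).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
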