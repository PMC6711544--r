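Package: neutralnets
Title: Mutational Robustness and Recombination on Neutral Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic selection-mutation-recombination dynamics for haploid
    populations on binary hypercube genotype spaces. Implements neutral
    fitness-landscape generators (mesa, percolation, sea-cliff, atoll and a
    synthetic graded stand-in for an empirical eight-locus landscape),
    recombination operators (uniform, one-point and communal crossover),
    mutational robustness and recombination-weight statistics, exact two-locus
    closed forms including the critical recombination rate, lumped
    Hamming-class solvers for large mesa landscapes with their asymptotic
    approximations, and a finite-population Wright-Fisher simulator. A small
    command-line interface exposes the solvers and landscape generators for
    shell pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
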