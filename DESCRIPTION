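Package: azacene
Title: Evolutionary Design and Charge-Transport Evaluation of Aza-Acene
    Organic Semiconductors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evolutionary exploration of the chemical space of
    aza-substituted acenes (cata-fused six-membered aromatic C/N ring
    systems) in search of n-type organic semiconductors.  Provides an
    exact hexagonal-lattice molecular representation with four graph
    transformation operators (addition, crossover, recombination,
    mutation), exhaustive enumeration of the search space with canonical
    deduplication, a generational evolutionary engine with elitism and
    tournament selection, reorganisation-energy and Schottky-penalised
    fitness functions behind pluggable molecular-property oracles, Marcus
    hopping-rate networks built from crystal structures with Kabsch dimer
    deduplication, rejection-free kinetic Monte Carlo electron mobility
    tensors via the Einstein relation, and Boltzmann-weighted
    energy-structure-function landscape statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ChemmineOB,
    ChemmineR,
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
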