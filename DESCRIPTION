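Package: rdabethe
Title: Random Domino Automaton on the Bethe Lattice
Version: 0.1.0
Authors@R:
    person("RDA", "Maintainers", email = "maintainers@rdabethe.org",
           role = c("aut", "cre"))
Description: Steady-state theory and Monte-Carlo simulation of the Random
    Domino Automaton (a stochastic forest-fire cellular automaton) on the
    Bethe lattice of coordination number 3. Provides the mean-field balance
    equations and their exact elimination-based solver for the solvable
    avalanche law mu_i = delta/i, the stability window in delta, the cascade
    recursion for the cluster-size distribution and its inverse problem,
    exact Motzkin and generalized (A036765) integer recurrences connected to
    the rescaled cascade, and a simulator on random 3-regular graphs and
    finite Cayley trees for empirical validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
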