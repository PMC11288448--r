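Package: moranbd
Title: Moran Birth-Death Dynamics on Directed Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the Moran Birth-death process on strongly
    connected directed graphs. Provides exact absorbing-Markov-chain solvers
    for fixation probability and absorption, fixation and extinction times;
    the neutral-drift N-equation system for single-mutant fixation
    probabilities; efficiently computable polynomial upper bounds on fixation
    time for strong selection, Eulerian graphs, arbitrary graphs via the
    minimum neutral fixation probability, and balanced graphs; a seeded Monte
    Carlo simulator with a randomized approximation-scheme sampling plan; and
    isomorphism-free enumeration of small strongly connected digraphs with
    census and landscape scans over mutant fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
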