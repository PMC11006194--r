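Package: moranamp
Title: Moran Processes and Amplifiers of Selection on Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying Moran Birth-death and death-Birth dynamics on
    weighted undirected networks. Computes exact fixation probabilities by
    sparse linear solves of the absorbing Markov chain, both on the full
    2^N configuration space and on symmetry-lumped chains for structured
    graph families (complete, star, fan, and composite two-chunk
    amplifiers). Provides a compiled Monte Carlo trajectory engine with
    seeded reproducibility, closed-form complete-graph baselines, node
    temperature and first-step survival bias, amplifier/suppressor
    classification, numerical verification of impossibility results for
    simultaneous Birth-death and death-Birth improvement, and a
    coarse-grained chunk-coupling approximation for rare-migration
    composite structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
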