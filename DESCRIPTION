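Package: dcjmoments
Title: Moment Estimators of Genome Rearrangement Distance Under the
    Double Cut-and-Join Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical estimation of the number of Double Cut-and-Join (DCJ)
    rearrangements separating two genomes with equal gene content, by the
    method of moments. Provides an exact closed-form expression for the
    expected number of breakpoints after k uniform random DCJ operations on an
    augmented genome, together with its analytic inversion; companion
    estimators imported from binary-sequence evolution (with the four-by-four
    substitution correction), from the random transposition walk on the
    symmetric group (expected permutation cycles, evaluated in
    arbitrary-precision arithmetic), and from sparse random multigraphs
    (expected component counts).  Includes genome representations as perfect
    matchings on gene extremities, observed and real breakpoint graphs with
    cycle statistics and the parsimony DCJ distance, a seedable DCJ
    Markov-chain simulator with coupled transposition and random-graph
    processes, exact brute-force oracles over small state spaces, readers and
    writers for UniMoG/GRIMM-style gene order files, and scripted simulation
    experiments comparing all estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
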