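Package: mayleonard
Title: Off-Lattice May-Leonard Simulations of Cyclic Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator for three-species cyclic (rock-paper-
    scissors) competition in continuous two-dimensional space with periodic
    boundaries.  Individuals move, predate and reproduce stochastically;
    reproduction is gated by a local carrying capacity that caps the number
    of individuals within the reproduction range.  The package provides a
    compiled Monte Carlo engine with cell-list neighbour search, recording of
    population time series, stationary summaries and mean-population scaling
    with the carrying capacity, discrete Fourier analysis of species-fraction
    oscillations with ensemble-averaged power spectra, peak-frequency
    extraction and logarithmic peak scaling, scripted scenario replications,
    snapshot export, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
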