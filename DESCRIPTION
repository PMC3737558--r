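Package: ringmix
Title: Monte Carlo Simulation of Co-Confined Ring and Linear Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of two hard-core bead chains
    (circular and/or linear) confined in a spherocylindrical container,
    modelling topological domains of bacterial chromosomes. Implements
    crankshaft moves with strict chain-crossing prevention, exact topological
    audits (Gauss linking number, Alexander determinant), axial overlap-length
    and contact-probability observables, and blocking-method error analysis
    for correlated Monte Carlo series. Demonstrates how linearising one of two
    co-confined polymers switches the pair from a segregated to a mixed state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
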