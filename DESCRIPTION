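Package: amrswitch
Title: Cooperative Antimicrobial Resistance in Randomly Switching
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exact stochastic simulation and analytic theory for the
    eco-evolutionary dynamics of a two-strain microbial community in which
    antimicrobial resistance is a thresholded public good. A resistant,
    enzyme-producing strain and a drug-sensitive strain compete under a
    logistic death rate whose carrying capacity switches at random between
    states of abundance and scarcity (dichotomous Markov noise). The package
    provides a Gillespie-exact simulator of the coupled demographic and
    environmental process, the mean-field and piecewise-deterministic
    (PDMP) dynamics, Moran-type fixation probabilities and mean coexistence
    times in static environments, transient-dip analytics with the
    optimal-eradication-region criterion, and ensemble machinery for
    fixation/coexistence phase diagrams and abundance distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
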