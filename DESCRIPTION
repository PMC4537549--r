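Package: sphingokin
Title: Compartmental Kinetic Modeling of Sphingolipid Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses compartmental reaction-network models of
    human sphingolipid metabolism. Provides a nine-compartment kinetic model
    of ceramide, sphingomyelin, sphingosine, their phosphorylated forms and
    glycosphingolipids, with mass-action transport and Michaelis-Menten
    enzymatic kinetics including sphingosine-1-phosphate inhibition.
    Implements deterministic simulation and steady-state stabilization,
    exact stochastic simulation, forward local sensitivity analysis with
    time-integrated sensitivity indices, Linear Noise Approximation of the
    stationary covariance with per-reaction variance decomposition, and
    Fisher-information-based parameter redundancy clustering with
    identifiability filtering. Includes an Alzheimer's-disease perturbation
    scenario and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    ape,
    xml2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
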