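Package: syncol
Title: Spatiotemporal Dynamic Flux Balance Simulation of Syngas Bubble
    Column Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synthesis gas (CO/H2/CO2) fermentation by acetogens
    in industrial bubble column reactors by coupling a constraint-based
    metabolic model, solved at every axial node as a lexicographic
    flux-balance linear program, to multiphase convection-dispersion mass
    balances for biomass, dissolved gases, gas-phase species, and secreted
    ethanol and acetate. Provides Monod-type gas uptake kinetics with
    product and CO inhibition, Henry's-law gas-liquid transfer, Danckwerts
    boundary conditions, a method-of-lines integrator with an embedded
    dense simplex solver, steady-state reactor metrics, parameter sweep
    and gas-recycle drivers, and readers for SBML (FBC) and COBRA-JSON
    metabolic models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
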