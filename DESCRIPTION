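Package: ldpmc
Title: Local-Density Potential Monte Carlo for Mesoscopic Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of single-site coarse-grained
    fluids whose potential energy is a local-density functional of an excess
    Helmholtz free energy (the Pagonabarraga-Frenkel construction), with the
    SAFT-VR Mie equation of state (third-order Barker-Henderson monomer
    perturbation plus a Wertheim four-site association term) as the free-energy
    backend and a square-gradient correction for the vapour-liquid interfacial
    tension.  Includes bulk-property solvers (pressure, vapour-liquid
    coexistence, isothermal compressibility), direct-coexistence slab builders,
    test-area surface-tension and test-volume pressure estimators, fluctuation
    compressibility, percent absolute average deviation scoring, and
    calibration of the square-gradient coefficient against a target
    surface-tension table with a cubic temperature fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
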