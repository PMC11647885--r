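Package: ohmd
Title: Classical Hydroxide Models and Stochastic Proton-Hopping Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Minimal periodic molecular dynamics for rigid TIP3P water with
    classical hydroxide-ion models (two-particle reduced-charge models and a
    three-auxiliary-particle lone-pair model), plus a stochastic Grotthuss
    proton-hopping layer with a threshold-Metropolis acceptance rule.
    Includes force-field parameterization by chi-squared steepest descent
    over Lennard-Jones parameters, alchemical solvation free energies by
    windowed free-energy perturbation, system builders for bulk water boxes
    and single-file water in (6,6) carbon nanotubes, and trajectory analyses:
    radial distribution functions, coordination numbers, Einstein diffusion,
    electrophoretic mobility, hydroxide tracking and hop/rattle
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
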