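Package: myoperf
Title: Personalized Coronary and Myocardial Blood Flow Modeling at Desk Scale
Version: 0.1.0
Authors@R:
    person("Maintainer", "Anonymous", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for personalizing coronary hemodynamics and myocardial
    perfusion models against clinical cardiac-function and perfusion-imaging
    targets. Provides closed-loop lumped-parameter (0D) circulation networks
    with coronary outlet boundary conditions and time-varying elastance heart
    chambers, constrained-constructive-optimization growth of synthetic
    vascular trees, Voronoi perfusion-territory mapping of myocardial blood
    flow, a single-compartment Darcy finite-element perfusion solver on
    tetrahedral left-ventricle meshes, multi-stage Nelder-Mead boundary
    condition tuning (cardiac function, then flow distribution with or
    without synthetic trees), along-branch fractional flow reserve, and a
    seed-reproducible synthetic patient generator so the full pipeline runs
    without clinical imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
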