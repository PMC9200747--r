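Package: dann
Title: Diabatic Neural-Network Potentials and Non-Adiabatic Dynamics for Photoswitches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fitting smooth diabatic Hamiltonian surrogates of excited-state
    potential energy surfaces and running trajectory surface-hopping dynamics on them.
    A symmetric 3x3 diabatic matrix is predicted from molecular geometry (either by an
    equivariant message-passing network or by an internal-coordinate descriptor
    network), diagonalized to yield adiabatic energies, and differentiated through the
    rotated-gradient identity to yield forces and non-adiabatic coupling vectors that
    stay well behaved at conical intersections. Includes fewest-switches and
    Zhu-Nakamura surface hopping, Nose-Hoover thermal sampling, committee-based active
    learning, an analytic azobenzene-like oracle potential for end-to-end validation,
    and observables for photoswitch screening (isomerization quantum yield, excited
    state lifetime, thermally averaged gaps, isomeric stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
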