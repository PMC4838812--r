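Package: wendling
Title: Simulation and Dynamical Analysis of an Extended Neural Mass Model
    of Epileptic EEG
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates depth-EEG-like output of the extended Wendling
    neural mass model, a four-subgroup (pyramidal cells, excitatory
    interneurons, slow dendritic and fast somatic inhibitory interneurons)
    lumped-parameter model widely used in epilepsy research.  Provides the
    full 10-equation system and a mathematically equivalent reduced
    8-equation formulation, fixed-step classical integrators (forward
    Euler, 4th-order Runge-Kutta) that reproduce the step-size-dependent
    variance artifact of treating the stochastic input as an ordinary
    forcing term, and a corrected stochastic forward Euler scheme whose
    output variance is stable across step sizes.  Includes equilibrium
    (nullcline) computation, Jacobian eigenvalue stability
    classification, saddle-node and stability-transition localization
    over the slow inhibitory gain, multi-phase scenario simulation of
    interictal-to-ictal progressions, DC-offset removal utilities,
    CSV/JSON writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
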