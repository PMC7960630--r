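Package: chemokin
Title: Keller-Segel Dynamics of Chemotactic and Chemokinetic Bacterial
    Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the spatio-temporal dynamics of bacterial populations
    that combine chemotaxis (tumble-rate bias toward attractant) with
    chemokinesis (concentration-dependent swimming speed) using an extended
    Keller-Segel drift-diffusion model. Provides the pointwise model terms
    (Hill-type speed response, chemokinetic and chemotactic drift speeds,
    Monod consumption, logistic growth), closed-form results (the threshold
    on the Hill exponent above which the chemokinetic drift dominates, and
    the zero-flux steady-state profile), a conservative finite-volume solver
    on 1D Cartesian and axisymmetric grids with adaptive explicit time
    stepping, constructors for three benchmark scenarios (fixed linear
    attractant gradient, self-generated gradient on an agar plate, transient
    attractant pulse), and observables for peak accumulation, integrated
    population size and front propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
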