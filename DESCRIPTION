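Package: aisx
Title: Axon Initial Segment Geometry and Neuronal Excitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and numerical tools relating the geometry of the axon
    initial segment (AIS) to neuronal excitability. Provides closed-form
    passive cable quantities (space constant, axial and input resistances
    under sealed-end, killed-end and finite-soma boundary conditions),
    spike-threshold theory for a point or spatially extended AIS derived
    from a fold bifurcation of the resistively coupled soma-axon system,
    Hodgkin-Huxley style channel kinetics with temperature correction, a
    compartmental cable simulator on branched morphologies with an implicit
    tree solver, and measurement protocols (rheobase and voltage-threshold
    bisection, voltage-clamp threshold, early-time input resistance,
    logarithmic threshold regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
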