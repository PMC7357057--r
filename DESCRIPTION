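Package: matrixrelease
Title: Dissolution-Diffusion Modelling of Drug Release from Spherical
    Matrix Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates drug release from a non-swelling spherical matrix
    loaded with dispersed solid drug particles when the dissolution rate is
    finite. Fickian diffusion of the dissolved phase is coupled to a
    Noyes-Whitney dissolution source whose available surface area follows a
    shape-dependent power law of the remaining solid concentration (planar,
    cylindrical or spherical particles). The package provides the stiff
    method-of-lines solver for the coupled equations, closed-form results
    (critical depletion time, surface solid concentration, and the
    pre-depletion series solution for planar particles), the classical
    spherical-matrix Higuchi model as the instantaneous-dissolution
    reference, and analysis tools that locate the zero-order
    (constant-release-rate) window and quantify the deviation of Higuchi's
    approximation from the finite-dissolution solution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
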