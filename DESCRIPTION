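Package: aneumt
Title: Finite-Volume Mass Transport in an Idealised Aneurysm with Selectable
    Convection-Diffusion Discretisation Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale finite-volume toolkit for blood-side mass-transport
    modelling in an idealised axisymmetric aneurysm.  Generates a body-fitted
    structured quadrilateral mesh with quality metrics, solves the steady
    laminar axisymmetric incompressible Navier-Stokes equations with a
    SIMPLE-type collocated pressure-velocity coupling, and advances an
    unsteady passive species mass-fraction equation on the frozen flow with
    any of four convection face-interpolation schemes (first-order upwind,
    power law, second-order upwind, QUICK) applied by deferred correction.
    Includes the hemispherical probe-extraction emulation with equal-height
    slab partitioning and volume weighting, synthetic reference generators
    (exact one-dimensional convection-diffusion benchmark, oblique-step
    false-diffusion fixture, pseudo-experimental sac fill-in series), and
    scheme-comparison metrics such as the time-averaged percentage
    difference of probe concentration series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
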