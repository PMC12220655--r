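Package: csfdrift
Title: Reduced-Order Modeling of Solute Dispersion in Oscillatory Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing long-time solute dispersion in time-periodic,
    spatially non-uniform incompressible flows, motivated by drug transport in
    the cerebrospinal fluid of the spinal canal. The package generates and
    validates divergence-free oscillatory velocity fields (manufactured
    stream-function flows, analytic pulsatile channel flow, and a small
    two-dimensional Navier-Stokes solver with a flow-rate-matching controller),
    computes the mean Lagrangian velocity both from the asymptotic
    streaming-plus-Stokes-drift formula and from direct particle tracking over
    one cycle, removes the non-solenoidal part of the trajectory-based drift by
    a Helmholtz projection, and integrates both the full oscillatory
    advection-diffusion equation and the reduced steady-advection transport
    equation, together with bolus dispersion diagnostics (center of mass, axial
    variance, effective hydrodynamic diffusivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
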