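Package: ibcms
Title: Immersed Boundary Cardiovascular Flow Simulation and Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale fluid-structure-interaction simulator for
    cardiovascular chamber flows built on the immersed boundary method:
    an incompressible Navier-Stokes solver on a periodic Cartesian grid
    (fractional-step projection with Crank-Nicolson viscous terms and an
    FFT pressure solve), Lagrangian elastic fiber boundaries coupled
    through the four-point regularized delta kernel, reservoir-pressure
    inflow and outflow ports, synthetic elastic-chamber fixtures (ellipse
    membrane, tethered cylinder, two-chamber ventricle with valve flaps
    and an E/A/S activation schedule), and hemodynamic diagnostics (port
    flow rates, z-vorticity, slice kinetic energy, chamber volume, vortex
    core counting, kinetic-energy peak detection).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
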