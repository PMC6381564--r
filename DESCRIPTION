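Package: pulseSI
Title: State-Dependent Pulse Vaccination in an SI Epidemic Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for an SI epidemic model with
    nonlinear incidence under state-dependent pulse vaccination and
    treatment. The continuous dynamics are interrupted by an impulsive
    control that fires whenever the infected level reaches a hazardous
    threshold, instantaneously vaccinating a fraction of susceptibles and
    treating a fraction of infecteds. The package provides the scaled
    planar vector field, equilibria and their linear classification, an
    event-detecting hybrid integrator, the successor (Poincare return)
    map on the phase line with order-1 periodic-orbit finding and orbital
    stability assessment, saddle-manifold shooting for the critical
    vaccination rate at which an order-1 homoclinic cycle exists, regime
    classification, named scenario fixtures, phase-portrait and
    time-series plotting with CSV data export, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
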