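Package: hemobond
Title: Bond-Graph Lumped-Parameter Simulation of Cardiovascular Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compositional bond-graph (0D) simulator for closed- and open-loop
    cardiovascular hemodynamics. Derives lumped resistance, compliance and
    inertance parameters from vessel geometry, assembles segment, junction,
    terminal (RCR Windkessel) and time-varying-elastance heart modules into a
    stiff ODE system, integrates it to a periodic state with a BDF solver, and
    validates the lumped solution against analytic limits and an in-package
    one-dimensional finite-volume blood-flow reference solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
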