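Package: rootflow
Title: Parametric Aortic-Root Hemodynamics with Stabilized Finite Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow through idealized parametric
    aortic-root geometries (surgical valve replacement, Y-incision annular
    enlargement, and valve-in-valve scenarios) with an equal-order stabilized
    finite-element incompressible Navier-Stokes solver, an orifice-plane valve
    model, two-element Windkessel and coronary boundary conditions, and a
    source-driven residence-time transport equation used as a stasis and
    thrombosis surrogate. Provides transvalvular metrics (peak velocity, mean
    pressure gradient, residence-time statistics) and a config-driven pipeline
    for multi-scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
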