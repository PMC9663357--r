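Package: tubecap
Title: Surface and Tubular Membrane Capacitance from Capacitive
    Transients in Low-Conductivity Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates the surface and tubular membrane capacitance of
    cardiomyocytes from whole-cell voltage-clamp capacitive currents
    recorded under low-conductivity (isotonic sucrose) extracellular
    solution.  Implements the lumped two-compartment RC equivalent
    circuit of a tubulated cell, its analytic step response and a
    stiff-capable numerical simulator with shaped pulse edges and
    pulse-train averaging, bi-exponential decomposition of the
    capacitive transient, and closed-form/iterative recovery of all
    eight circuit elements (access resistance, lumen resistance,
    surface and tubular membrane resistance and capacitance, reversal
    voltages) together with the tubular capacitance fraction and
    quality-control criteria for sucrose wash-in.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
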