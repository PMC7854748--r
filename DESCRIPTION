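Package: capkin
Title: Kinetics of Reversible Safety-Cap Protection in [FeFe]-Hydrogenase
    Film Electrochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the reversible anaerobic inactivation of
    [FeFe]-hydrogenases such as CbA5H by protein film electrochemistry.
    Implements the three-state AAI kinetic scheme (A1 <-> A2 <-> Hinact)
    and its two-state reduction, exact propagation of the master equation
    under piecewise-constant potential programs, a current model for
    potential-step chronoamperometry, qualitative cyclic-voltammetry
    hysteresis simulation, multistart least-squares fitting and model
    comparison, parameter-recovery studies, an oxygen-exposure
    residual-activity protocol with a four-species damage model, a
    synthetic-data generator for all of the above, plain-text trace I/O,
    and safety-cap geometry metrics (cysteine-sulfur to distal-iron
    distance, rigid superposition) for deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    deSolve,
    jsonlite,
    bio3d,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
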