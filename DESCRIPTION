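Package: poreflux
Title: Nonlinear Ion Transport and Voltage-Driven Gating in Beta-Barrel Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for nonlinear ionic transport through
    beta-barrel protein nanopores such as aerolysin. Predicts open-pore
    current-voltage curves and rectification from a one-dimensional
    steady-state electrodiffusion model of a charged pore lumen, simulates
    stochastic voltage-dependent two-state gating of single pores and pore
    ensembles (memristive hysteresis, synaptic pulse protocols), implements
    the a.c. ensemble trace-analysis pipeline (pore-count estimation, cycle
    averaging, closed-state probability, closing rate, rectification factor,
    d.c. level segmentation), and estimates ionic currents from framewise ion
    trajectories. Includes a synthetic-data generator for closed-loop
    validation of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
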