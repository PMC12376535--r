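Package: clampsim
Title: Simulation and Correction of Whole-Cell Voltage-Clamp Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detailed equivalent-circuit model of whole-cell patch-clamp
    voltage-clamp experiments, including amplifier compensation circuitry:
    series-resistance compensation, supercharging (prediction), fast and slow
    capacitance compensation, voltage-offset compensation, recording filter
    delays, and post-hoc leak subtraction. Provides stiff ODE simulation of the
    artifact model with pluggable Hodgkin-Huxley-type fast sodium current
    models, piecewise-constant voltage protocols, current-voltage (I-V) curve
    summaries, population-of-models studies (Latin hypercube and distributional
    condition sampling) quantifying the bias of averaged I-V curves against the
    artifact-free reference, artifact-parameter fitting to recorded traces, and
    action-potential/cable simulations propagating sodium-current
    mischaracterization into upstroke velocity and conduction velocity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
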