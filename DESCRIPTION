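Package: afcirc
Title: Lumped-Parameter Hemodynamics of Atrial Fibrillation under Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A closed-loop lumped-parameter (0D) model of the four-chamber
    heart with dynamic valves and the systemic and pulmonary circulations,
    driven beat-by-beat by prescribed RR intervals. Includes a synthetic
    atrial-fibrillation RR-interval generator (exponentially modified
    Gaussian with a correlated pink-noise Gaussian component), MET-graded
    exercise parametrizations, beat-wise hemodynamic metrics (stroke volume,
    ejection fraction, cardiac output, stroke work, tension-time index,
    arterial pressures), the variation comparative index used to contrast
    slower versus higher resting heart rates, and a parameter sensitivity
    scan. Simulations integrate a stiff ODE system with an adaptive
    multistep solver using compiled model code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    deSolve,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
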