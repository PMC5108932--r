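Package: fiberAP
Title: Action-Potential Excitability and Conduction in Cardiac Cell Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation of electrical excitability in guinea-pig ventricular
    myocytes and one-dimensional monodomain fibers of gap-junction-coupled
    cells. Implements a 22-state ionic cell model with the inward-rectifier
    potassium conductance (G_K1) and fast sodium conductance (G_Na) exposed
    as free parameters, a sealed-end discrete cable of coupled cells, stiff
    ODE integration with square-pulse stimulus scheduling, and measurement
    protocols for stimulus-current thresholds, conduction velocity, passive
    space constants and action-potential duration. Includes parameter-sweep
    drivers for independent and reciprocal (tandem) G_K1-G_Na modulation and
    analytic discrete-cable oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, deSolve, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
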