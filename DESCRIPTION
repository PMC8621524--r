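Package: ecdischarge
Type: Package
Title: Simulation and Analysis of Recurrent Epileptiform Discharges in
    Entorhinal Cortex
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-population mean-field model of recurrent epileptiform
    discharges of the kind recorded in cortical slices under proepileptic
    conditions.  The model couples the membrane voltages of a main and a
    spontaneously bursting ("noisy") neuronal population to extracellular
    potassium and intracellular sodium dynamics, an electrogenic Na+/K+
    pump, fast and slow use-dependent synaptic resources, and transient
    and persistent activity-dependent conductances; a scheduled
    sigmoid-shaped block emulates bath application of a calcium-permeable
    AMPA receptor antagonist.  A compiled Euler integrator with Poisson
    shot-noise conductance input produces full traces.  The analysis
    layer provides threshold-based discharge detection, input conductance
    estimation from hyperpolarizing current steps, single-exponential
    post-discharge decay fits, inwardly rectifying current-voltage curve
    fits and the rectification index, plus synthetic fixture generators
    with stored ground truth for validating every analysis operation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
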