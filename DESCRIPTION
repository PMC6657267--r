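Package: compclone
Title: Multi-Compartment Stochastic Simulation of Ordered Driver
    Mutations in Cancer Clonal Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven stochastic simulation of cancer clonal evolution
    across tissue compartments (e.g. breast duct, circulation, bone), where
    driver mutations must be acquired in a compartment-defined order to
    become effective, metabolic mutations accelerate the cell cycle, and
    stemness-dependent support windows gate asymmetric division, symmetric
    division, apoptosis and migration.  Includes a deterministic
    master-equation integrator on the truncated state space that serves as
    a correctness oracle for the simulator, a compartment-path probability
    model deriving the ordered driver sets, drug-perturbation experiments
    by partial state signature, exact combinatorial targeting fractions,
    and scenario files packaging the breast-to-bone case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
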