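Package: zymoCharge
Title: Surface-Charge Transfer Design and Zymogen Activation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rational transfer of a homolog's surface-charge pattern
    onto a target protein and for analysing zymogen activation kinetics. The
    design pipeline combines affine-gap global sequence alignment, detection of
    charge-differing positions, Shrake-Rupley solvent accessibility, distance
    filters against the activation peptide, and hydroxyl-avoiding (PTM-safe)
    substitution rules, with a screened-Coulomb surface potential for
    comparing charge patterns. The kinetics module provides the autocatalytic
    activation-cascade ODE model, activation-rate estimation from activity
    time courses, Michaelis-Menten fitting, and unit conversions via specific
    activity. A synthetic-data module generates planted-truth homolog pairs
    with toy structures, cascade time courses and velocity datasets so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
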