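Package: cgmpScreen
Title: Kinetic Modeling and Combinatorial Perturbation Screening of the
    NO-cGMP Signaling Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic mass-action kinetic model of the nitric
    oxide-soluble guanylyl cyclase-cGMP-phosphodiesterase signaling pathway
    under oxidative stress (12 molecular species, 13 rate constants), with a
    combinatorial perturbation screen that ranks all single, paired, and
    triple rate-constant inhibitions by time-integrated cGMP. Combination
    effects are evaluated against Bliss independence and classified by
    isobologram curvature (additive, synergistic, antagonistic) on 11x11 and
    11x11x11 dose matrices. Includes a calibrated default parameter set, a
    synthetic-data module for parameter ensembles and noisy time courses, and
    a reproducible pipeline driver with TSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
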