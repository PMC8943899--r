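Package: dp5
Title: Standalone Probabilistic Verification of Molecular Structures from
    13C NMR Prediction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the DP5 probability: a calibrated, standalone
    probability that a single proposed molecular structure is correct given
    its experimental 13C NMR spectrum and calculated chemical shifts.
    Per-atom prediction-error densities are estimated by kernel density
    estimation over a reference error database, weighted by Gaussian-kernel
    similarity between rotation- and translation-invariant atomic
    environment descriptors. Atomic probabilities are Boltzmann-averaged
    over conformers, combined through a geometric-mean molecular
    probability, and mapped to a posterior probability of correctness by an
    empirical Bayesian calibration fitted on correct and incorrect
    structure-spectrum pairs. Includes a permutation cross-validation
    benchmark, a diastereomer ranking mode, and a synthetic corpus
    generator for fully self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
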