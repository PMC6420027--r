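Package: goalbabbling
Title: Goal Babbling Simulation and Motor-Synergy Analysis for Redundant
    Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates direct inverse-model learning (Goal Babbling) on a
    redundant three-joint planar reaching task, generates synthetic
    human-like training sessions with planted ground truth, and analyses
    motor-synergy formation: windowed principal-component analysis of
    postures in motor space, variance-explained trajectories, solution
    location between home postures, degree-of-freedom loadings, summed
    variance, and from-scratch repeated-measures statistics (two-way
    rmANOVA with partial eta-squared, exact sign test, Wilcoxon
    signed-rank, Friedman test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
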