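Package: o2supply
Title: Oxygen Supply Capacity and Critical Oxygen Pressure from
    Intermittent-Flow Respirometry
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts sealed-chamber oxygen depletion traces from
    intermittent-flow respirometry into maximum metabolic rate (MMR),
    oxygen supply capacity (alpha) and the critical oxygen partial
    pressure for maximum metabolism (PcMax = MMR/alpha).  Includes
    seawater oxygen solubility and unit conversion utilities, a
    mechanistic trace simulator with known ground truth for validating
    the estimators, microbial background correction, allometric mass
    scaling by nonlinear least squares, automatic bin-width selection
    for the alpha estimator, and a permutation-based statistical layer
    (one-way ANOVA with Tukey post hoc, linear regression, Lilliefors
    and Levene tests).  A pipeline driver orchestrates simulate,
    process, metrics and stats stages with fixed CSV/JSON file
    contracts and end-to-end determinism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
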