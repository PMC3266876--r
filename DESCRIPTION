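Package: wormrepro
Title: Macro-Level Kinetic Modelling of C. elegans Reproduction Under
    Chronic Heat Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic gamete-flow kinetics of Caenorhabditis elegans
    self-reproduction (full and quasi-steady-state mass-action models, an
    oocyte-death variant with its equivalence mapping, and exponential
    temperature laws for the rate constants), an individual-based cohort
    simulator reproducing the destructive/longitudinal egg-counting
    protocol with robust and non-robust physiological classes, maximum
    likelihood estimation of the kinetic parameters from time-resolved
    egg counts, held-out temperature prediction, and the accompanying
    brood-size statistics: two-component mixture fits (normal+normal and
    normal+exponential), parametric-bootstrap normality testing, and
    permutation tests on coefficients of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
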