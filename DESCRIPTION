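Package: bwmort
Title: Mixture-Based Modeling of Birthweight-Specific Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a birthweight distribution as a finite normal mixture and
    estimates a separate birthweight-specific mortality curve within each
    component by maximum likelihood conditional on the fitted mixture
    (generalized parametric mixtures of logistic regressions). Combines
    per-sample fits across multiple, possibly overlapping, samples from the
    same population into overall risk estimates with logit-scale confidence
    intervals featuring simulation-based bias adjustment and an
    overlap-corrected calibration constant; provides within- and
    between-population mortality odds ratios, covariate-within-component
    probabilities, a seeded synthetic-data generator, and a coverage
    simulation study for calibrating the interval constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
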