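Package: bspm1d
Title: Bayesian and Classical Statistical Parametric Mapping for 1D Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hypothesis testing over whole one-dimensional continua such as
    time-normalized kinematic or kinetic trajectories. Implements pointwise
    JZS (Jeffreys-Zellner-Siow) default Bayes-factor t-tests with point and
    interval null hypotheses on the standardized effect size, converts them
    to posterior probability maps, and controls the false discovery rate by
    q-values defined as cumulative means of posterior error probabilities.
    Classical random-field-theory SPM{t} inference (residual smoothness
    estimation, field-wide critical thresholds, cluster-extent p-values) is
    provided for side-by-side comparison, together with smooth Gaussian
    random field simulators, gait-like example-data generators, and
    simulation-based continuum power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
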