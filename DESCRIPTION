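Package: grtsim
Title: Simulation and Small-Sample Inference for Multiple-Period
    Group-Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous outcomes for balanced two-condition
    multiple-period parallel group-randomized trials under repeated measures
    ANOVA and random coefficients generating mechanisms, for both
    cross-sectional and cohort designs.  Fits the standard grid of linear
    mixed analytic models (variance components, compound symmetric,
    unstructured and diagonal-unstructured covariance structures) by
    unconstrained restricted maximum likelihood, tests the time-by-condition
    interaction with Kenward-Roger or between-within small-sample F tests,
    and estimates type I error rates by Monte Carlo.  Includes closed-form
    conversions between variance components and the within-period ICC,
    between-period ICC, cluster autocorrelation and individual
    autocorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pbkrtest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
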