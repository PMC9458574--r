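Package: pupilexplore
Title: Pupillometric and Behavioral Analysis of Directed Exploration in
    Probabilistic Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying deliberate (directed) exploratory choices in a
    two-alternative probabilistic learning task with concurrent pupillometry.
    Provides a synthetic session generator (learning agent, lognormal response
    times, 1 kHz pupil signal with phasic responses, tonic drift and blink or
    spike artifacts), a tabular session file format, the full pupil
    preprocessing chain (derivative-based artifact detection, linear
    interpolation, 50-ms binning, within-subject z-scoring, response-locked
    epoch extraction and exclusion), learning-criterion and choice-type
    classification (high-payoff, pre-low-payoff, low-payoff and
    post-low-payoff trials), linear mixed models with crossed random
    intercepts, step-down model selection, type-III tests with Satterthwaite
    denominator degrees of freedom, Tukey-adjusted marginal-mean contrasts,
    pointwise time-course testing with false-discovery-rate window selection,
    and permutation tests for Pearson correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
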