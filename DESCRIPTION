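Package: mentakin
Title: Kinematics, Scoring and Bayesian Models for Triangle-Animation
    Mentalising Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-session (drug/placebo) crossover experiments that
    probe mental-state attribution with animated-triangle stimuli. Provides a
    synthetic cohort generator with known ground-truth effects (trajectories,
    animation ratings, emotion-recognition, working-memory and walking
    measures), kinematic feature extraction (mean speed and mean jerk from
    positional time series, observer-animator jerk-difference similarity),
    the target-minus-non-target accuracy score with its binary and
    percentage-accuracy transforms and drug-minus-placebo change scores, and
    a registry of Bayesian hierarchical mixed-effects models (Gaussian,
    two-component Gaussian mixture, and truncated Student-t response
    families) fitted by MCMC with posterior summaries, sign probabilities
    and Pareto-smoothed importance-sampling leave-one-out model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
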