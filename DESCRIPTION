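Package: soctask
Title: Sense-of-Control Driven Task Switching in Hierarchical
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a situational sense of control (SoC) - composed of a
    forward-model prediction error and a rollout-based need-for-control
    signal - and uses it inside a hierarchical reinforcement-learning agent
    that switches between two concurrently running 'Collect Asteroids'
    subtasks. Provides the gridworld simulator with difficulty and
    input-noise manipulations, a deterministic forward model, the SoC
    arithmetic, a proximal-policy-optimization trainer for sub- and
    meta-agents, baseline switching policies, and an evaluation suite
    computing voluntary task-switching behavioral metrics (success rates,
    engagement ratios, switch counts, per-decision switching ratios) with
    block-wise ANOVA, Bartlett and Holm-adjusted post-hoc statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
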