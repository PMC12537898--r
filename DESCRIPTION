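Package: mbema
Title: Model-Based Reinforcement Learning and Real-Life Drinking Intentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and fits the two-step sequential decision task with a
    hybrid model-free/model-based reinforcement-learning agent, derives
    model-based reward-prediction-error components and a regression-based
    model-based (MB) score from stay/switch behaviour, generates synthetic
    ecological-momentary-assessment (EMA) records of daily alcohol intake and
    weekly drinking intentions with a hurdle log-normal process, and runs
    cross-level moderation analyses (linear and logistic mixed-effects models)
    linking model-based behaviour and simulated regional neural signatures to
    the implementation of drinking-reduction intentions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
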