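Package: svogaze
Title: Social Value Orientation Estimation Under Inequality Control with
    Eye-Tracking Process Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how option inequality biases estimates of
    social value orientation (SVO) in binary money-allocation tasks.
    Generates SVO Ring and inequality-controlled stimulus batteries,
    simulates participants' softmax choices, response times and region-of-
    interest fixation streams, computes fixation-based process measures
    (total fixation count, breadth of information search, Payne Index,
    dwell-time advantage), estimates altruism and choice-sensitivity
    parameters with a hierarchical Bayesian softmax model sampled by an
    adaptive Metropolis-within-Gibbs algorithm, and provides paired
    condition comparisons with Jeffreys-Zellner-Siow Bayes factors,
    bootstrap parallel multiple-mediator models with a logistic outcome,
    and mixed-effects logistic gaze-choice models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
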