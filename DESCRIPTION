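Package: partialpress
Title: Partial-Error Detection from Analog Keyboard Trajectories in Response-Conflict Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring response conflict with analog (hall-effect)
    gaming keyboards that report continuous key depression in [0, 1].
    Reconstructs per-key analog trajectories from change-only event logs,
    extracts response times and partial errors (sub-threshold activation of
    the incorrect response key before the overt response), and applies the
    standard exclusion and participant-aggregation pipeline for the response
    time Concealed Information Test (RT-CIT) and the modified Sternberg task.
    Includes exact generators for both task designs, a seeded trajectory
    simulator with known ground truth for end-to-end validation, and a
    statistical layer with JZS-prior Bayes-factor mixed ANOVA and t tests,
    a rank-based Bayes factor, maximum-likelihood ex-Gaussian reaction-time
    models, LexTALE scoring, and the arcsine transform.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
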