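Package: brpriming
Title: Scoring and Validation of Binocular Rivalry Imagery-Priming Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring trial-level binocular rivalry imagery-priming
    sessions used in the behavioural assessment of mental imagery and
    aphantasia. Implements the classic priming score (proportion of non-mixed
    rivalry trials congruent with the imagery cue), an improved score that
    half-weights mixed-percept trials in the numerator while fully weighting
    them in the denominator, a perceptual stability score over consecutive
    rivalry trials, and a priming-minus-stability difference score. Includes
    session validation rules (mock-trial compliance gate, mixed-trial
    thresholds), a generative simulator of imagery-primed rivalry cohorts with
    ground-truth imagery strength, statistical validation procedures
    (dependent-correlation comparison, variance ratios, Welch tests with
    Hedges g, median-split analyses, DerSimonian-Laird random-effects
    meta-analysis of correlations), and a bounded simulation of the
    questionnaire-versus-task correlation ceiling.
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
    withr
Suggests:
    knitr,
    metafor,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
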