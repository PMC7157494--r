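Package: mrtmod
Title: Micro-Randomized Trial Simulation and Time-Varying Moderation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates six-month micro-randomized trials of mobile-health
    push notifications (weekly four-arm randomization, daily Bernoulli
    delivery, alternating tip/insight message buckets, daily mood, step and
    sleep outcomes with missing-at-random attrition) and analyses them with
    a multicategorical weighted-and-centered least-squares estimator of
    time-varying effect moderation. Inference uses participant-clustered
    sandwich variance; daily-level multiple imputation is pooled with
    Rubin's rules; fitted moderation coefficients are turned into
    effect-versus-moderator curves with square-root retransformation to
    natural units and standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
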