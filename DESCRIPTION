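Package: artidelta
Title: Frame-Differencing Analysis of Articulatory Preparation in Ultrasound Tongue Imaging
Version: 0.1.0
Authors@R:
    person("artidelta", "maintainers", email = "artidelta@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tongue movement from ultrasound frame stacks by
    frame-to-frame Euclidean pixel differencing (the "Delta" technique), time-locking the
    resulting movement traces to trial events in a question-answer turn-taking paradigm,
    averaging them per participant and condition, and testing condition differences with a
    cluster-based sign-flip Monte-Carlo permutation test. Includes a synthetic
    articulatory-ultrasound generator (trial timelines, latent tongue kinematics, rendered
    speckle-noise frame stacks) that emulates the statistical structure of a two-condition
    (early- vs late-planning) quiz experiment, plus per-condition response-time summaries
    and a crossed random-intercepts linear mixed-effects model of response times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
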