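Package: starsit
Title: Outcome Measures and Statistics for Robot-Assisted Seated Posture Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the outcome measures of a three-arm (physical reality,
    augmented reality, virtual reality) robot-assisted seated posture training
    study and the statistics used to compare the arms: functional reach test
    scores from the eight-direction postural star sitting test, sitting
    workspace polygon areas, center-of-pressure total excursion, mean velocity
    and approximate entropy, the high-intense-activity rate of training, reach
    task scores, and uniform 7-point Likert questionnaire normalization.
    Includes zero-phase Butterworth preprocessing, a split-plot (mixed
    between-within) ANOVA layer with Bonferroni post-hoc tests and partial
    eta-squared effect sizes, and a seeded synthetic-cohort generator that
    emulates the study design so the whole pipeline is testable end to end
    without human recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    signal,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
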