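Package: implearn
Title: Simulation and Analysis of Implicit-Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing implicit-learning experiments
    that combine a sugar-factory dynamic system control (DSC) task with an
    alternating serial reaction time (ASRT) task. Provides the task engines
    (the hidden production law with clamping and random error, the circular
    worker-input scale, alternating pattern/random stimulus streams with
    balanced random trials, and the inclusion/exclusion generation task), a
    synthetic-participant cohort generator with controllable learning,
    awareness, response bias and negligence, scoring of all dependent
    measures (trials on target, confidence by outcome, per-block median
    reaction times and accuracy, triplet coding, cross-task learning
    indices), data-reduction screens and conscious-knowledge criteria,
    Monte-Carlo and exact chance baselines, and a mixed-design ANOVA engine
    with Mauchly's sphericity test, Greenhouse-Geisser correction and
    generalized eta squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
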