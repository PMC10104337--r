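Package: chasesim
Title: Pursuit-Evasion Stimulus Generation and Analysis for Chasing-Perception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates and analyses "wolf chasing sheep" displays used in
    visual psychophysics studies of animacy perception. Discs move on an
    eight-direction grid inside a bounded arena; the chasing disc (wolf) is
    driven by a direct-chasing, sheep-mimicking, or sheep-interception
    policy, the chased disc (sheep) circles the arena perimeter, and
    distractors either random-walk or chase invisible targets so that their
    kinematics match the wolf's. Includes trial curation and labelling
    rules, Monte-Carlo catch-rate estimation with Wilson confidence
    intervals, displacement-correlation and proximity cue statistics, a
    synthetic observer that stands in for human participants, and the
    response-level analyses (identification rate versus chance, exact
    binomial test on correlation-control choices). Trials round-trip
    through plain CSV/JSON files and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
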