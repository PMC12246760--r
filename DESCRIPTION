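Package: swipesense
Title: Screening Swipe-Gesture Telemetry for Anxiety and Depression Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for digital phenotyping from mobile-game
    swipe gestures. Reads per-session swipe event logs (JSON) and GAD-7/PHQ-8
    questionnaire tables, cleans and aggregates per-swipe kinematics and
    contact-area pressure into per-participant feature vectors, prunes
    collinear features, and screens the remainder against anxiety and
    depression scores with Spearman rank correlations. Ships a seeded
    synthetic cohort generator (touch traces, device-motion streams, item
    responses, planted effects) so the whole pipeline is testable without
    access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
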