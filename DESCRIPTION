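Package: mothslip
Title: Roll-Based Sideslip Maneuvers in Hawkmoth Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for direct lateral maneuvers
    ('sideslips') in hovering hawkmoth flight. Provides a quasi-steady
    blade-element simulator of a flapping moth with independent left and
    right wing kinematics and free roll/lateral/vertical body dynamics; a
    synthetic-observation generator that renders flights into digitized
    3D landmark sets at four stroke phases with configurable noise and
    multi-camera pixel projections; direct linear transformation (DLT)
    camera calibration, triangulation and wand diagnostics; extraction of
    body Euler angles, wing sweep/elevation/pitch angles, stroke
    amplitudes, left-right asymmetries and wingbeat-scale derivatives
    from landmark sequences; and the statistical core relating roll
    orientation to lateral acceleration and wing asymmetries to roll
    velocity, including zero-intercept least squares, random-intercept
    mixed models fitted by restricted maximum likelihood, an AICc model
    selection cascade, contribution percentages, damping time constants
    and percentile-binned t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
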