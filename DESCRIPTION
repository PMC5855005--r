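Package: gaitphase
Title: Real-Time Gait Phase Detection from Ground Contact Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gait phases (stance, swing) and gait events (heel-strike,
    heel-off) from two-channel ground contact force signals measured by force
    sensitive resistors under the ball and heel of the foot. Implements a
    self-tuning triple-threshold algorithm that re-estimates its low, middle
    and high thresholds once per gait cycle from the cycle's force extrema,
    so that contact detection adapts online to the wearer and to changes in
    walking speed. Also provides three fixed-threshold comparison methods
    (body-weight fraction, global-extrema span, averaged per-cycle extrema),
    a rule-based phase/event labeller, per-sample reliability scoring with
    grid search over the tuning proportions, and a seeded synthetic gait
    force generator for end-to-end testing without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
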