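Package: homingfields
Title: Analysis of Hippocampal Firing Fields During Homing by Path Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing rodent behavior and hippocampal single-unit
    activity in an automated homing task in which a mouse leaves a home base,
    searches a circular arena for a movable lever box, presses the lever, and
    homes back to the base. The package segments sessions into trials, journeys,
    and search/at-lever/homing paths; computes path metrics (length, duration,
    speed, complexity) and homing error at the arena periphery; builds 2D firing
    rate maps, 1D firing rate histograms with spatial information scores, and
    single-trial firing rate matrices; transforms positions into lever-centered
    coordinates under Cardinal, Bridge, and Lever directional reference frames;
    classifies lever-box-anchored firing fields; estimates per-trial directional
    drift of anchored fields and its circular coupling with homing direction;
    quantifies remapping through firing-rate-map similarity of cell pairs; and
    classifies units as putative pyramidal cells or interneurons. A synthetic
    session generator with full ground truth (injected field parameters,
    per-trial drifts, homing errors) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
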