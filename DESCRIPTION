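Package: echoSync
Title: Correspondence Analysis of Thermal-Video and Ultrasonic-Acoustic Bat Detections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how often flying bats are seen on thermal
    video but not heard on ultrasonic detectors. Implements a thermal-video
    target detector (background subtraction, blob tracking, proximity and
    flight-path classification), an echolocation-pulse detector and
    call-structure metric suite (interpulse interval, pulse rate, bandwidth,
    modulation, search-phase extraction, call-type flags), time-window
    matching of the two event streams into nightly correspondence tallies,
    and the associated statistics (nightly proportions, Pearson correlation,
    exact tests on r-by-c contingency tables with Bonferroni control, and
    sampled-airspace geometry). A seeded synthetic-data generator simulates
    nights of bat passes with controllable silent-flight probability,
    renders them as thermal frame stacks, and propagates their calls
    through a parametric acoustic channel, so the full pipeline can be
    exercised and the silent fraction recovered without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Software, Visualization
RoxygenNote: 7.3.3
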