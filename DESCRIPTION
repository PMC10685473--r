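Package: footmodel
Title: Multi-Segment Kinetic Foot Model for Clinical Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a four-segment (hindfoot, midfoot, forefoot, hallux)
    kinetic foot model for optical motion capture gait analysis. Reads marker
    trajectories (TRC, long-format CSV) and force-plate records, constructs
    segment-fixed coordinate frames from an eleven-marker foot set,
    computes intersegmental x-z-y Cardan angles, the medial longitudinal
    arch height/length ratio, and joint moments and powers by Newton-Euler
    inverse dynamics with single-plate center-of-pressure crossing
    ("CPcross") masking. Includes coefficient-of-multiple-correlation
    waveform reliability statistics and a synthetic rigid-segment gait
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
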