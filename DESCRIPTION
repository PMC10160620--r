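Package: pdgait
Title: Speed-Matched Gait Analysis from In-Shoe Vertical Ground Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes multichannel in-shoe vertical ground reaction force
    recordings (Physionet gaitpdb-style text files) into temporal and kinetic
    gait features, their stride-to-stride variability (coefficient of
    variation) and left-right asymmetry (symmetry index), and compares
    speed-matched Parkinson's disease and control cohorts with unpaired
    Student's t-tests and a permutation-thresholded one-dimensional
    statistical-parametric-mapping t-test over the stance-normalized force
    curve. Includes a synthetic gait generator with known ground-truth events
    and features so the whole pipeline is testable without the original
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
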