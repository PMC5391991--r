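Package: srttaware
Title: Individualized Threshold Detection of Explicit Awareness in Serial
    Reaction Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to detect the incidental development of explicit sequence
    awareness during serial reaction time tasks (SRTT) from response
    latencies alone.  A per-subject baseline (mean and SD of early or random
    key presses) anchors an individualized latency threshold
    (mean - z * SD); a subject is classified as explicitly aware when the
    one-sided upper confidence bound of their per-sequence-repetition mean
    latency drops below the threshold, optionally for two consecutive
    repetitions.  Includes pseudorandom sequence generation with adjacency
    and finger-run constraints, a calibrated synthetic cohort simulator with
    ground-truth awareness onsets, sensitivity/specificity sweeps over the
    z-score grid, signed-area quantification of ERP component amplitudes
    (early N1, late N1, P2, P3) with peak-block identification, and
    Spearman-based neurobehavioral correlation between behavioral awareness
    onset and ERP peak timing.
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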