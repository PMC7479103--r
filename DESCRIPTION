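Package: larvaquant
Title: Quantification of Drosophila Larval Locomotion, Nerve Conduction and
    Axon Wrapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based ethogram classification of crawling Drosophila larvae
    (stops, head bends, turns, coiling) from tracker-style posture tables,
    per-larva locomotion statistics including peristalsis frequency and the
    300-frame coiling clip histogram, conduction-velocity estimation from
    dual-electrode extracellular nerve recordings by the distance/delay
    quotient with iterative Grubbs outlier pruning, and axon morphometry
    (circular-equivalent radius, size histograms, wrapping index) from
    electron-microscopy cross-section annotations. Seeded synthetic-data
    generators for larval tracks, extracellular traces and nerve sections
    give every stage a ground-truth parameter-recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
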