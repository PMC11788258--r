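Package: pbtrack
Title: Tumor Tracking with Simulated Integrated-Mode Proton Radiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pencil-beam-scanning proton radiography of moving
    phantoms and analyses the resulting radiograph frames for tumor
    tracking. Provides geometric thorax and slab phantoms with
    water-equivalent-thickness (WET) ray queries, a synthetic scintillator
    detector with top/lateral/distal camera views, pristine Bragg-peak
    extraction and depth-to-WET conversion, frame-by-frame WET image
    reconstruction, strip-wise Otsu segmentation with centroid tracking
    against a programmed periodic motion, and a scan-pattern interplay
    artifact study quantified by ellipse eccentricity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
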