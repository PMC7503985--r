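Package: ndci
Title: Confidence-Interval Classification of High-Resolution Microendoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies high-resolution microendoscopy (HRME) images of the oral
    epithelium as neoplastic, benign, or "cannot classify". A semantic-segmentation
    U-Net (implemented in vectorized base R) excludes image regions without visible
    nuclei; nuclei in the remaining regions are segmented and scored by size and
    eccentricity; the number of abnormal nuclei per square millimetre is compared to
    a decision boundary through an exact Clopper-Pearson binomial confidence
    interval, yielding a classifier with a reject option. Includes a seeded
    synthetic-phantom generator with ground-truth nuclei, region masks and simulated
    raters, a coverage-probability validation experiment for the interval formula,
    and biopsy-level evaluation utilities (confusion tables, predictive values,
    two-proportion tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
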