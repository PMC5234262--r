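Package: torusseg
Title: Chronic-Wound Image Segmentation by Synthetic Frequencies and Toroidal Contrast Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments chronic-wound (pressure ulcer) photographs without an initial
    contour. A per-pixel synthetic frequency f = 1/A^r computed from the grayscale
    amplitude drives a toroidal-geometry contrast decomposition of the image; sweeping
    the frequency parameter r yields a stack of contrast levels, each binarized with a
    self-contained Otsu threshold optimizer. Accumulated level contours are refined with
    standard morphology (closing, hole filling, component filtering) into the final
    wound mask. Includes a seeded phantom generator producing wound-like RGB images
    with exact ground truth, and evaluation of masks by digital image (Pearson)
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
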