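Package: spherequant
Title: Automatic Detection, Counting and Area Quantification of
    Cell-Derived Spheres in Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A batch pipeline for brightfield and phase-contrast images of
    sphere-forming cell cultures (multiwell plates and microfluidic
    devices). Images are contrast-homogenized (CLAHE plus Gaussian
    smoothing), candidate sphere regions are proposed from a Gabor
    filter-bank texture response, and each region is segmented with Otsu
    thresholding, Sobel edge detection and morphological cleanup.
    Detected spheres are numbered deterministically, measured in
    calibrated square micrometers, and written to annotated images and a
    CSV report. A seeded synthetic-image generator with pixel-exact
    ground truth supports validation without real data, and sphere
    formation efficiency is computed from counts of seeded cells.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
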