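Package: deepwise
Title: Minority-Class Copy-Paste Augmentation and Evaluation for Cell
    Instance Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for preparing bone-marrow aspirate microscopy images
    for plasma-cell instance segmentation. Reads and writes VGG Image
    Annotator (VIA) polygon annotations, rasterizes polygons to instance
    masks and traces masks back to polygons, performs percentile contrast
    stretching and removal of unstained (non-plasma) cells, augments the
    minority cell class by extracting annotated cells, transforming them
    and pasting them onto existing training images with gradient-domain
    blending restricted to a narrow edge band so cell interiors are
    preserved bit-exactly, and evaluates predicted against ground-truth
    instance masks via greedy IoU matching (mean precision, mean recall,
    mean IoU). A seeded synthetic blood-smear image generator makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Matrix,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
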