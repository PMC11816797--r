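Package: siliquant
Title: Silique Morphometrics from Instance Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts fruit (silique) morphometric traits from per-instance
    binary segmentation masks: projected area, skeleton length, maximum
    diameter from the Euclidean distance transform, and a disk-stack volume
    approximation. Includes instance-level quality control (connected
    component and skeleton-spur filters), sample-level phenotype aggregation
    (means, percentiles, relative standard deviation) with exclusion
    bookkeeping, paired treatment tests and broad-sense heritability
    estimates for mapping-ready phenotype export, COCO-style detection and
    segmentation evaluation (average precision and recall over
    intersection-over-union thresholds), and a synthetic capsule generator
    with analytically known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
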