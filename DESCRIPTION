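Package: cordscan
Title: Atlas-Free Cervical Spinal Cord Segmentation on Sagittal T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments the cervical spinal cord on midsagittal
    T2-weighted magnetic resonance images without an anatomical atlas.  The
    pipeline selects the midsagittal slice of a sagittal series by pairwise
    symmetry, classifies pixel intensities with a Gaussian-mixture fit of the
    gray-level histogram, detects a chain of anatomical structures (spinal
    cord, longitudinal ligaments, ligamentum flavum, vertebral column) as
    banded dynamic-programming optimal paths, labels vertebral bodies and
    intervertebral disks by region growing and anatomical knowledge, and
    finally extracts the anterior and posterior cord edges with compound
    fitness functions.  Ships with a seeded synthetic phantom generator with
    full ground truth and with standard segmentation agreement metrics
    (Jaccard, Dice, Hausdorff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    mclust,
    optparse
Config/testthat/edition: 3
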