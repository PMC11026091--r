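Package: mmpipe
Title: Mother Machine Image Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular analysis pipeline for mother machine (microfluidic
    single-cell trap) time-lapse experiments. Detects and crops growth
    channels from raw phase-contrast fields of view, subtracts an aligned
    empty-channel background, segments cells with a scaled Otsu threshold,
    distance transform, morphological cleanup and random-walker boundary
    refinement, tracks lineages with a decision tree built on the a priori
    constraints of binary fission in a one-ended channel, and derives
    cell-cycle physiology statistics (birth and division length, added
    length, generation time, elongation rate, septum position). Includes a
    synthetic experiment generator with ground-truth masks and lineage
    trees, and a segmentation evaluation harness based on per-cell
    intersection-over-union matching and the Jaccard index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
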