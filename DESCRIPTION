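Package: emtracer
Title: Unsupervised Segmentation and 3D Reconstruction of Peroxidase-Labeled
    Processes in Serial-Section Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing genetically labeled, electron-dense (DAB-stained)
    neuronal processes through serial-section electron microscopy volumes
    without supervised training. Per-section clustering-based (Otsu) global
    thresholding with marker-specific modulation extracts dark 2D candidate
    segments, which are measured, filtered by area and major-axis bounds,
    pruned of large imaging artifacts, and linked across sections (including
    across gaps) by a k-nearest-neighbour centroid search into labeled 3D
    reconstructions. Includes a synthetic serial-section phantom generator
    with ground truth, recall and contrast-to-noise evaluation, and an
    ROI-proposal stage for targeted high-resolution re-imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
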