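Package: octseg
Title: Gradient-Based Segmentation of Corneal Layer Interfaces in OCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automatic segmentation of corneal layer interfaces
    (air-epithelium, epithelium-stroma, endothelium-aqueous) in 2D B-scan
    and 3D volume optical coherence tomography images. Implements
    preprocessing (apex detection, region-of-interest cropping, horizontal
    and central artifact suppression, adaptive Wiener denoising), coarse
    anterior-surface estimation by maximizing a boundary function over
    A-scan local-maxima candidate pairs, center-outward gradient-based
    refinement with geometric-distribution decay weighting, shift-based
    estimation of deeper interfaces, a direct 3D extension ordered by a
    city-block geodesic distance transform, a synthetic phantom generator
    with known ground truth, and mean unsigned surface positioning error
    (MSPE) evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
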