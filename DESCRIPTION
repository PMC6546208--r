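Package: cellmorph
Title: Texture, Irregularity and Spreading Morphometrics for Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction for segmented single-cell microscopy images:
    band-based actin-distribution measures, grayscale fractal dimensions over
    four edge binarizations, Haralick-style gray-level co-occurrence (GLCM)
    texture statistics, Fourier boundary waviness and roughness, geometric
    and convex-hull shape measures, and Zernike moment magnitudes.  Includes
    an analysis layer (Pearson correlation heat maps, per-category principal
    component analysis and primary-principal-component selection via worst-case
    Welch t-tests) and a synthetic single-cell image generator so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pheatmap,
    jsonlite,
    optparse
Config/testthat/edition: 3
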