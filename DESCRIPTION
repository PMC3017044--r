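Package: fracland
Title: Higuchi Fractal Dimension of Image Landscapes and Contour Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the complexity of grayscale images and closed planar
    contours with Higuchi's fractal dimension. A 2-D image is reduced to 1-D
    "landscape" series of normalized row and column gray-value sums; a closed
    contour is reduced to its 1-D radial signature about the centroid. The
    fractal dimension of these series is estimated globally or in a sliding
    window, and per-case results can be aggregated into group-level cohort
    reports (for example benign versus malignant mass contours). Includes
    generators for fractional Brownian motion, anisotropic synthetic textures
    and synthetic contour cohorts with controlled roughness, used to validate
    the estimator against the relation D = 2 - H.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
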