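Package: mmitex
Title: Mask Matching Image Texture Features for Wood Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Texture features for grayscale images based on higher-order
    local autocorrelation (HLAC) and its Mask Matching Image (MMI)
    extension. Enumerates the distinct HLAC mask patterns of a 3x3
    displacement window (25 masks up to order 2, 223 up to order 8),
    computes per-mask binary match images, and derives statistical
    features from their connected components (SSMMI) as well as
    run-length width/height histograms (length histogram, LH). Includes
    the repeated stratified holdout evaluation protocol with 1-NN
    (L1 distance) and linear C-SVC classifiers, a synthetic generator of
    wood-cross-section-like textures for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
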