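Package: rhizotrack
Title: In Situ Root Phenotyping from Rhizotron Scanner Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative in situ root phenotyping from time-series
    flatbed-scanner images of roots grown against a transparent rhizotron panel.
    Provides image catalog handling and dpi-based physical calibration, a
    classical and a small trainable encoder-decoder (atrous spatial pyramid
    pooling with a sub-pixel convolution decoder) root segmenter, skeleton-based
    extraction of root length, average diameter, surface area, volume and root
    length density, net growth rate dynamics, root hair length and density
    quantification from high-resolution scans, emergence/senescence event
    detection with Kaplan-Meier lifespan analysis, and a seeded synthetic
    rhizotron image generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
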