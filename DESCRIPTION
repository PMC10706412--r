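Package: csanose
Title: Colorimetric Sensor Array Image Analysis for Edible-Oil
    Adulteration Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An optoelectronic-nose analysis toolchain for colorimetric
    sensor arrays (CSA). Segments dye indicator spots from pre- and
    post-exposure photographs of a six-dye array (Otsu thresholding,
    morphological area opening, erosion, hole filling, reading-order
    labeling), builds per-spot RGB difference-map fingerprints and
    18-element color feature vectors, and detects and grades edible-oil
    adulteration with principal component analysis and a support vector
    machine tuned by random search over kernel, kernel scale, box
    constraint and standardization. Includes a synthetic sensor-array
    image generator with ground truth for end-to-end validation, and a
    command-line interface covering segmentation, fingerprinting,
    exposure-time optimization, simulation, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
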