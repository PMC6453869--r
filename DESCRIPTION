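Package: condensia
Title: Quantitative Image Analysis of Mesenchymal Condensations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and morphometric profiling of mesenchymal
    condensations in micromass culture images, and high-content
    quantification of geometrically constrained condensations in
    microgroove time-lapse fluorescence imaging. Provides a watershed
    segmentation pipeline for brightfield micromass images with
    minima-imposition control of over-segmentation, eleven shape
    descriptors (including roundness, boundary roughness, circumscribed
    occupancy and nearest-neighbour distance) with linear-discriminant
    ranking between condensation classes, an axis-averaged intensity
    profile quantifier measuring condensation length and width by full
    width at half maximum and cell density by peak prominence, backward
    tracking of condensations across live-imaging series, and a
    synthetic image generator with exact ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
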