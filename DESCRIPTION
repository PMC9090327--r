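Package: shapecat
Title: One-Shot Shape Categorization Analysis for Closed-Contour Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for generative one-shot categorization
    experiments on 2D closed-contour drawings. Provides a contour geometry
    kernel (arc-length resampling, chord-cut part segmentation, straightness
    classification), similarity-space construction from rater placements,
    part-correspondence and cyclic part-order analysis, aggregation of tiered
    distinctiveness paintings with a distribution-matched randomized null,
    distinctive-part-swap stimulus synthesis, the accompanying statistical
    toolkit (one-sided binomial tests, Cohen's h, sample-size calculators),
    and a synthetic-data generator that emulates exemplar shapes, drawn
    variations and rater responses so every stage can be exercised without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    mgcv,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
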