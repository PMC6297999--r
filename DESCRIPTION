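Package: seedhalo
Title: Quantification of Seed Mucilage Halos and Seed Morphometry from
    Stained Agarose Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised image analysis for myxospermous seed phenotyping.
    Quantifies the halo of soluble seed-coat mucilage released around each
    seed on a toluidine-blue-O-stained agarose plate together with the
    morphometric parameters of the seed itself. Images are thresholded in
    the HSV colour space with species defaults (an iterative-intermeans
    automatic threshold suggester is included), connected components are
    labelled line by line from the top of the plate, halos outside a
    plausible size range are discarded, eleven shape descriptors are
    computed per object in calibrated millimetre units, and each seed is
    paired with its halo either by sowing rank or by centroid containment
    to yield the adjusted mucilage content (halo area over seed area).
    A deterministic synthetic-plate generator with analytic ground truth
    supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jpeg,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
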