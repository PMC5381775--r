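Package: stainring
Title: Pixel-Wise Stain Classification and Radial Profiling of Micropatterned Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies dual-chromogen-stained stem-cell micrographs into
    adipogenic (Oil Red O positive), osteogenic (Fast Blue positive) and
    stain-negative areas at pixel level with a support vector machine on RGB
    features, and quantifies the radial distribution of each class inside
    circular micro-confinements by segmenting label maps into coaxial rings
    of fixed physical thickness. Includes a seeded synthetic stained-colony
    simulator with exact ground-truth labels so every stage of the pipeline
    can be validated without microscopy data, an end-to-end pipeline runner
    with reproducible manifests, and ggplot2 graphics for radial profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
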