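Package: fiberburden
Title: Asbestos Fiber Burden Quantification in Lung Tissue with Poisson
    Counting Statistics and Reference-Material Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes asbestos fiber concentrations in lung tissue from
    scanning-electron-microscope membrane-filter counting sessions
    (fibers per gram of dry tissue), with exact Poisson counting
    uncertainty, analytical sensitivity, filter-loading arithmetic and
    examination planning.  Implements precision and trueness verification
    against certified lung-tissue reference materials (BCR-665, BCR-666)
    using chi-squared repeatability checks and combined-uncertainty
    trueness bounds, and ships a seeded synthetic counting-session
    simulator (Poisson or gamma-mixed per-field deposition, stop rules)
    for method evaluation without real specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
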