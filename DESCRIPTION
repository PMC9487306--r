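Package: subarcvmat
Title: Sub-Arc Collimator Angle Optimization for Single-Isocenter VMAT
    Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Planning-time collimator angle optimization for single-isocenter
    coplanar volumetric modulated arc therapy (VMAT) of multiple brain
    metastases. Target structures are projected into the beam's eye view at
    every control point of an arc, conformal multi-leaf collimator (MLC)
    apertures are fitted, and an MLC conformity index (MCI) is mapped over
    control point and collimator angle. Each arc is then segmented into
    sub-arcs by exact dynamic programming under span and count constraints,
    and the collimator angle maximizing the summed MCI is selected per
    sub-arc, mitigating the island-blocking problem of multi-target plans.
    Also included: dose-volume plan-quality indices (conformity, homogeneity
    and gradient index, arc-weighted field size), a synthetic multi-lesion
    head-phantom and dose generator, and a bundled 20-case reference cohort
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
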