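Package: cortikin
Title: Area-Conserving Kinematics of the Apical Organ of Corti
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry-based kinematic model of the cross-section of the
    apical organ of Corti. Given an outer-hair-cell contraction and two
    dimensionless extensibility parameters (Deiters' cell and Hensen-cell
    contour), the package solves for the area-conserving deformation of the
    fluid spaces (tunnel of Corti, space of Nuel, outer tunnel) and of the
    Hensen-cell body, the latter modelled as a constrained planar elastica
    with preferred curvature. It derives reticular-lamina displacement,
    Hensen-cell motion, outer-hair-cell somatic rotation, the critical
    Deiters'-cell extensibility at which reticular-lamina motion vanishes,
    and the operating-point gain that modulates inner-hair-cell
    stimulation. Includes a calibrated guinea-pig apex reference geometry,
    parameter-region classification, sweep utilities and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
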