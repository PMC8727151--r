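Package: rootshear
Title: Root Reinforcement of Soil in Direct Shear: Waldron-Type Modelling
    and Shear-Zone Thickness Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing root-reinforced soil in direct shear.
    Implements a Waldron-type fibre-reinforcement model extended with
    spatially non-uniform and displacement-dependent shear-zone thickness,
    an automated tri-linear changepoint estimator that converts
    three-dimensional displacement fields (as produced by digital volume
    correlation of X-ray computed tomography scans) into per-position
    shear-zone thickness and growth maps, root-path length measurement and
    comparison with the tri-linear extension formula, back-analysis of the
    limiting root-soil interface stress from measured shear stress records,
    and synthetic generators for displacement fields, root maps and stress
    records with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
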