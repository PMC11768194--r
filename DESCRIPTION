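Package: crumblab
Title: Bread Crumb Image Analysis, Colour Difference, and MixoLab Curve
    Parameterization
Version: 0.1.0
Authors@R:
    person("Crumblab", "Developers", email = "crumblab@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of composite-flour bread
    studies: segmentation and size-classification of crumb air cells
    (pores) in bread-slice photographs, CIELAB total colour difference
    (Delta E, CIE76) with perceptual band classification and
    substitution-level trend fitting, extraction of the full Chopin
    MixoLab parameter vector (C1-C5, slopes, stability, gelling
    mid-point) from torque/temperature traces, one-way ANOVA with Tukey
    HSD compact letter displays, and seeded synthetic-data generators
    (ground-truthed crumb scenes, parametric torque curves, replicate
    colour readings) so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    jpeg,
    png,
    stats,
    utils,
    viridisLite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
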