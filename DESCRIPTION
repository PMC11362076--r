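Package: canopyLevels
Title: Green-Band Level Classification to Reduce Soil and Leaf-Shadow
    Interference in UAV Hyperspectral Canopy Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating crop leaf nitrogen content from UAV
    hyperspectral reflectance cubes in the presence of soil and leaf-shadow
    interference. Implements ENVI cube input/output, per-spectrum Gaussian
    and Savitzky-Golay pretreatments, an unsupervised vegetation mask, a
    two-stage ten-level classification of vegetation pixels by green-band
    (550 nm) intensity that isolates sunlit canopy, twenty standard
    vegetation indices, correlation screening of indices against leaf
    nitrogen content with compact-letter ANOVA tables, and regression
    models (multiple linear, principal component, partial least squares and
    support vector regression). A scene simulator with ground-truth
    sunlit/shaded/soil masks makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    multcomp,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
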