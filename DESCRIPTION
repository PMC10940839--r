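Package: microwellr
Title: Automated Monitoring of Microtissue Cultures in Square-Microwell Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for noninvasive monitoring of microtissue (spheroid)
    cultures in square-microwell array plates from brightfield images:
    random-forest pixel classification over a multi-scale image filter bank,
    Otsu thresholding and distance-transform watershed declumping of
    microtissue objects, microwell grid extraction with lattice snapping,
    centroid-in-polygon occupancy calling, particle size distribution
    statistics (D10/D50/D90, span, predicted tissue volume), factorial
    design-of-experiments analysis of liquid-handling parameters, and a
    synthetic plate-image generator with paired ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    mgcv,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
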