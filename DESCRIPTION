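Package: afmtrace
Title: Quantification of Amyloid Secondary Nucleation from AFM Topographs
Version: 0.1.0
Authors@R: person("afmtrace", "maintainers", email = "afmtrace@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify amyloid-beta fibril and oligomer morphology
    from atomic force microscopy (AFM) height maps: scanline flattening,
    object segmentation, sub-pixel fibril backbone tracing, height-based
    diameter and length measurement, stacked-object height subtraction,
    adsorption-site classification (edge / backbone / substrate), RMS
    roughness (Rq) fingerprinting of fibril generations, and catalytic
    activity classification (dormant / active / superspreader). Includes a
    synthetic topograph simulator (ground-truth scenes, tip-sample grayscale
    dilation, raster scan artifacts) so that every pipeline stage can be
    validated against known geometry without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
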