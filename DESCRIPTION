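Package: hipposhuttle
Title: Spatial Modelling and Image Quantification of YAP/TAZ
    Nuclear-Cytoplasmic Shuttling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reaction-diffusion modelling of Hippo-pathway effector
    (YAP/TAZ) shuttling between nucleus and cytoplasm on pixel geometries
    derived from fluorescence microscopy. Implements two pathway
    topologies (cytoplasmic versus nuclear phosphorylation), an explicit
    forward-time centred-space solver run to steady state, particle-swarm
    parameter estimation against max-normalized target images, and a scan
    of the nuclear phosphorylation/dephosphorylation ratio. Also provides
    the accompanying image-quantification pipelines (nuclear/cytoplasmic
    ratio with cell-density stratification, proximity-ligation dot
    counting by compartment, immunohistochemistry tile positivity), a
    z-score gene-signature activity index for time-course expression
    data, and seeded synthetic-data generators for all inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    tiff,
    png,
    randomForest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
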