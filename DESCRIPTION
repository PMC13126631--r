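Package: afmstate
Title: Simulated High-Speed AFM Imaging and Conformational State Inference
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interpreting high-speed atomic force microscopy (HS-AFM)
    height maps of proteins. Renders pseudo-AFM images from coarse-grained bead
    models with a sphere-capped-cone tip by collision detection, emulates
    line-scan temporal lag and additive white noise, defines ordered
    conformational states of a structural ensemble by principal component
    analysis and Gaussian-mixture clustering, trains a multitask vision
    transformer autoencoder that simultaneously denoises images and classifies
    states, and provides exhaustive-grid rigid-body fitting by pixel
    correlation for comparison. Includes a synthetic hinge-motion ensemble
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    mclust,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
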