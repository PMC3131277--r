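Package: microcrackct
Title: Segmentation and 3D Morphometry of Microcracks in Trabecular Bone
    Micro-CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies micrometer-thin planar microcracks in
    high-resolution micro-CT volumes of human trabecular bone. Provides
    ring-artifact and intensity pre-processing, Hessian-based enhancement of
    planar structures, a planarity-guided nonlinear (bilateral-type) filter,
    hysteresis thresholding with 3D connected-component labelling,
    moment-based best-fitting-ellipsoid morphometry (crack length, width),
    direct local-thickness maps (maximal inscribed spheres), discrimination
    of microcracks from osteocyte lacunae, specimen-level morphometry
    (BV/TV, SMI, crack and lacunar densities), virtual 2D sectioning for
    3D-vs-2D comparisons, and a synthetic trabecular phantom generator with
    voxel-level ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
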