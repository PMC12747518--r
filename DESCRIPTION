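Package: gyralkit
Title: Differential-Growth Simulation and Morphometric Comparison of
    Cortical Folding Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cortical gyrification in silico: a
    morphoelastic finite-element simulator of differential tangential
    growth in a soft bilayer solid (multiplicative decomposition of the
    deformation gradient, compressible neo-Hookean energy, explicit
    quasi-static relaxation with self-contact), shape-index and
    curvature morphometry of folded surfaces, landmark-matched
    quasi-conformal disk parameterization, and a p-norm similarity
    index for comparing folded surfaces. Includes seeded generators for
    brain-like synthetic solids, analytic curvature test patches and
    synthetic sulcal landmark curves, plus readers and writers for
    common ASCII mesh formats (OFF, PLY, STL, legacy VTK, node/ele).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
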