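Package: stainfit
Title: Rigid-Body Fitting and Handedness Determination for Low-Resolution EM Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multi-start rigid-body fitting of atomic structures into
    low-resolution (negative-stain) electron microscopy density maps.
    Provides MRC2014 map input/output, simulation of density maps from
    coordinates by Gaussian convolution, map mirroring for handedness
    (mirror-image) determination, four fit-quality metrics (overlap,
    cross-correlation, Chamfer distance, envelope/Dice score), greedy
    clustering of fits into representatives, fit significance, pairwise
    combination of two-body fits with clash filtering, validation of
    assemblies against crosslinking mass-spectrometry restraint tables,
    solvent-accessible and buried interface areas, and a synthetic
    benchmark generator with ground-truth poses and planted crosslink
    violations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
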