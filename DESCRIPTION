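Package: scutefold
Title: Growth-Induced Skin Folding Mechanics of Reptile Head Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale toolkit for studying mechanical self-organization of
    reptile head-scale patterns. Provides a finite-strain neo-Hookean
    tetrahedral finite-element simulator with multiplicative (morphoelastic)
    growth, self-contact and viscous quasi-static relaxation of a bilayer
    skin adhered to rigid bone; synthetic generators for layered meshes,
    light-sheet-style 3D image phantoms and spherical nanoindentation
    curves; a volumetric segmentation stage (3D Canny edges, oriented point
    clouds, implicit surface reconstruction, epidermis thickness mapping,
    principal-curvature cell detection); Hertzian load-displacement fitting
    with fit-quality filtering; and fold-pattern quantification (discrete
    mean curvature, crease network extraction, polygonal domain
    segmentation, spectral wavelength, cross-species comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
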