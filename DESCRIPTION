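Package: neurofold
Title: Mechanical Simulation of Fetal Brain Folding and Sulcal-Pit Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the spatiotemporal evolution of sulcal pits in
    the folding fetal brain. Implements a differential-tangential-growth finite
    element model (multiplicative growth decomposition with neo-Hookean
    hyperelasticity) on bilayer cortex/white-matter tetrahedral meshes, sulcal
    depth estimation via a depth potential function, sulcal basin and pit
    extraction by watershed-by-flooding, two-stage sulcal-pit point-cloud
    matching with reweighted random walks, and the similarity degree of sulcal
    pits (SDSP) together with cohort-level analyses. Includes a synthetic
    brain-like geometry generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'mesh-core.R'
    'match.R'
    'cohort.R'
    'surface.R'
    'growth.R'
    'io.R'
    'pits.R'
    'synthgeom.R'
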