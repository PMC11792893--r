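Package: amphistom
Title: Stomatal Patterning and CO2 Diffusion in Amphistomatous Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial statistics and biophysical modelling of stomatal
    arrangement on the two surfaces of amphistomatous leaves. Quantifies
    how far observed stomatal point patterns lie between complete spatial
    randomness and the ideal equilateral-triangular grid (nearest-neighbour
    index and a Monte-Carlo dispersion index), tests abaxial-adaxial
    coordination through pixel-wise correlation of nearest-stomate distance
    rasters, relates guard-cell length to the Voronoi supply zone of each
    stomate, and computes the photosynthetic advantage of offsetting stomata
    between surfaces with a two-dimensional porous-medium reaction-diffusion
    model of CO2 transport solved by the finite element method. Includes
    generators for synthetic leaf surfaces (random, hard-core, conditioned
    triangular grids, coordinated surface pairs) used as null and ideal
    references throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    knitr
Config/testthat/edition: 3
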