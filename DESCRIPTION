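Package: phenomesh
Title: Triangle-Mesh Morphometrics for 3D Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of plant morphological parameters on triangle-mesh
    surface models such as those produced by structured-light scanners.
    Provides mesh input/output (PLY, OBJ, STL), surface area, enclosed
    volume and surface-to-volume ratio for closed meshes, geodesic
    distances along mesh edges (Dijkstra) and over the surface (fast
    marching), a band-based centerline algorithm that estimates the length
    of twisted leaves along their midline, isotropic remeshing with a
    resolution-versus-error study, detection and filling of small holes
    left by thorns, and deterministic synthetic mesh generators (UV
    spheres, twisted ribbons, perforated ribbons, primitives) with
    analytic ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
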