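Package: perfterra
Title: Perfusion Territories and 1D Blood Flow on Cerebrovascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologic supply-and-demand modelling of the cerebrovascular
    system. Assigns brain-tissue elements to arterial source points by a
    connectivity-constrained weighted Voronoi tessellation, converts territory
    mass to blood-flow demand via regional cerebral blood flow (CBF), and
    solves the steady reduced one-dimensional flow problem on the vascular
    network (including circle-of-Willis loops) for per-artery flows and
    pressures. Also provides a Murray's-law comparator model, a
    truncation-radius sensitivity sweep, perfusion-territory probability and
    majority maps over co-registered cohorts, and deterministic synthetic
    circle-of-Willis phantoms for testing. Reads and writes VTP/VTU (VTK XML
    ASCII), Gmsh MSH, NIfTI, and a documented JSON network dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
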