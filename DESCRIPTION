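Package: skeletoolkit
Title: Skeleton-Based Neuroanatomy: Morphometry, Synapse Flow, NBLAST
    Similarity and Template-Space Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data model and analysis toolbox for neuron skeletons with
    synapse annotations. Reads and writes SWC skeletons, offline
    CATMAID-style compact-skeleton JSON, Wavefront OBJ neuropil meshes,
    landmark-pair tables and NBLAST scoring matrices. Provides skeleton
    morphometry (summary statistics, Strahler order, spine, geodesic
    distances, Sholl profiles, resampling and pruning), synapse-flow
    centrality with axon/dendrite/cell-body-fibre compartment splitting,
    NBLAST vector-cloud similarity with hierarchical clustering and
    principal-axes alignment, landmark-based affine and thin-plate-spline
    transforms with numerical inversion, mirroring and a bridging graph
    over named template spaces, and mesh volumetrics (volumes,
    point-in-mesh tests, in-volume pruning, convex hulls and alpha
    shapes, overlap and potential-synapse scores). Deterministic
    synthetic-data generators make every analysis testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RANN,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
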