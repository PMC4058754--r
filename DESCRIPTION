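Package: agnet
Title: Attributed-Graph Networks for Functional Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs attributed functional connectivity networks from
    resting-state fMRI volumes (voxel power selection, ROI clustering,
    correlation-thresholded edges, per-node signatures), measures
    inter-subject network dissimilarity by minimum-cost assignment of node
    signatures (Munkres algorithm), embeds subjects with metric-stress
    multidimensional scaling, and classifies diagnostic groups with a
    polynomial-kernel support vector machine, including leave-one-out and
    train/test evaluation protocols, a correlation-threshold sweep, standard
    graph-feature baselines (degree, generalized topological overlap,
    clustering coefficient, local efficiency, rich-club curve), and a
    synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
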