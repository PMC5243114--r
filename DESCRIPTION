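Package: oticmap
Title: Lineage, Spatial and Level-Set Analytics for 3D+Time Otic Vesicle Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and analyse inner-ear neurosensory lineages
    from 3D+time light-sheet cell-tracking data. Provides a synthetic
    otic-vesicle data generator (two-shelled ellipsoidal epithelium with
    domain-dependent division rates, anterolateral-to-posteromedial neuroblast
    delamination and hair-cell differentiation), track-table input/output with
    fixpoint rigid registration and 16-to-8-bit dynamic-range mapping, lineage
    forest construction and backtracking, delamination and differentiation
    event detection with timing, ordering, clonal and progenitor-map
    statistics, fixed-radius local density and nearest-neighbour distance
    estimators, a generalized subjective-surface (level-set) cell segmentation
    solver using a semi-implicit finite-volume scheme, and Lagrangian
    triangulated-surface reconstruction of vesicle walls from point clouds
    with enclosed and shell volume estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
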