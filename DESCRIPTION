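Package: vemtools
Title: Desk-Scale Analysis Tools for Volume Electron Microscopy Connectomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Raster, graph and geometry operations for whole-brain volume
    electron microscopy connectomics at desk scale: supervoxel
    agglomeration-graph proofreading with append-only edit logs and
    deterministic replay, skeleton-based segmentation evaluation and
    oversegmentation consensus, post-processing of tissue-classifier maps
    into soma candidates and defocus masks, synaptic contact-area and
    profile-length measurement with object-wise detector validation,
    connectome edge-list assembly with recurrency checks, skeleton
    morphometrics, X-ray-mask-targeted tile planning, block-wise affine
    landmark registration, and a synthetic phantom generator that makes
    every stage testable without acquisition data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
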