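Package: graphmqa
Title: Graph-Coupled Network Quality Assessment for Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level quality assessment of protein structure models with
    a graph-coupled encoder-decoder network. Provides backbone PDB reading and
    writing, ground-truth lDDT labelling, designed topological descriptors
    (triangular location, residue-level contact order, invariant voxelization),
    residue-graph node and edge features, a deterministic mock protein
    language-model embedding provider, a graph-transformer / invariant-point
    attention / equivariant-GNN encoder with a dilated-convolution decoder
    predicting per-pair distance errors and per-residue lDDT, a composite
    training loss with a desk-scale training loop built on an internal
    reverse-mode autodiff engine, and a synthetic decoy generator based on
    graded dihedral perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
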