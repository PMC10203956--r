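Package: gstn
Title: Graph Subgraph Transformer Networks for hERG Blocker Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small molecules as hERG potassium-channel blockers or
    non-blockers from SMILES strings with a graph subgraph transformer network
    (GSTN): the molecular adjacency matrix is decomposed into predefined
    subgraphs (whole molecule, Murcko scaffold, aromatic rings, heteroatom
    edges), combined through learnable per-head attention weights into
    meta-path matrices whose product drives a symmetrically normalized graph
    convolution and a multilayer-perceptron decision head. Includes single-
    and dual-threshold IC50 labeling schemes, baseline models (graph
    transformer, molecular graph convolutional network, ECFP with a support
    vector machine), stratified cross-validation with confusion-matrix and
    ROC metrics, applicability-domain leverage, interpretability exports of
    the learned meta-path matrices, and a synthetic molecule/activity
    generator with planted substructure rules and activity cliffs. Chemistry
    (SMILES parsing, canonical atom ranking, Murcko scaffolds, circular
    fingerprints) is delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    e1071,
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' or 'python3'
Config/testthat/edition: 3
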