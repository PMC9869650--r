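Package: designbench
Title: Stratified Evaluation of Fixed-Backbone Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarking toolkit for fixed-backbone protein sequence design
    (inverse folding). Reads per-residue amino-acid prediction matrices,
    protein backbone structures (PDB) and a CATH-annotated dataset map, and
    computes a class-imbalance-aware metric report: per-amino-acid recall,
    precision, F1, one-vs-rest AUC, Shannon entropy and prediction bias;
    accuracy, macro-precision, macro-recall, BLOSUM62 similarity and top-3
    accuracy stratified per chain, per secondary-structure state and per CATH
    fold class and architecture; accuracy-versus-resolution correlation; and
    true-versus-predicted Ramachandran comparisons. Includes a simplified
    Kabsch-Sander hydrogen-bond secondary-structure assigner, a DSSP file
    importer, and deterministic synthetic fixtures (ideal-geometry backbones
    built from torsion angles, configurable predictors, toy benchmarks) so the
    whole pipeline is testable without external binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    bio3d,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
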