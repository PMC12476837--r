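Package: ProFunGraph
Title: Protein Function Prediction by Dual-Laplacian Regularized Matrix
    Factorization on Heterogeneous Protein-GO Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations for proteins by learning
    on a three-layer heterogeneous graph: a protein-protein similarity layer
    fused from alignment-free pseudo amino-acid composition (PseAAC) sequence
    features and neighbour-augmented TF-IDF domain-architecture profiles, a
    binary protein-GO annotation layer, and a GO-GO semantic layer built from
    weighted is_a / part_of links of the ontology DAG. Annotations are imputed
    by non-negative matrix factorization with graph-Laplacian regularization on
    both the protein and the term side, initialized from a truncated SVD with
    leakage-safe masking of test proteins. Includes readers with the standard
    experimental filters (distinct-method PPI support, evidence-code and
    annotation-count term filters), CAFA-style evaluation (protein-centric
    Fmax, micro AUC and AUPR) under LOOCV, k-fold, homology-aware and
    cold-start protocols, and a synthetic proteome generator with planted
    functional modules so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
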