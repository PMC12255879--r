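Package: bindgraph
Title: Environment-Aware Heterogeneous-Graph Prediction of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R:
    person("Binding", "Graph Maintainers", email = "maintainer@bindgraph.dev",
           role = c("aut", "cre"))
Description: Multimodal prediction of protein-ligand binding affinity (pKd/pKi)
    from structure and sequence. Featurizes protein, pocket and ligand inputs
    into fixed-shape padded matrices, builds pocket, ligand and heterogeneous
    complex graphs carrying three virtual environment nodes loaded with global
    biochemical descriptors (pI, GRAVY, TPSA, logP, H-bond counts, ...), and
    couples four encoder branches (dilated convolutions over the protein
    sequence, pocket-ligand cross-attention, an E(n)-invariant graph network
    over the pocket, an attentive fingerprint over the ligand) with a
    three-step SAGE-based heterogeneous message-passing scheme over the
    complex graph. Includes a reverse-mode autodiff core, Adam training with
    plateau learning-rate decay, the five standard affinity-regression metrics
    (R, RMSE, MAE, SD, CI), a fully synthetic complex generator with a planted
    affinity law, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
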