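# bindgraph

Environment-aware heterogeneous-graph prediction of protein–ligand binding
affinity in R.

## The problem

Predicting the binding affinity (−log10 Kd/Ki, "pKd") of a protein–ligand
complex is central to structure-based drug discovery. Sequence-only models
miss 3-D interaction geometry; plain structural graph models miss the global
biochemical *environment* — charge, hydrophobicity, polar surface area,
hydrogen-bonding capacity — that modulates non-covalent binding. `bindgraph`
implements a multimodal architecture that combines both and makes the
environment explicit as **virtual graph nodes**.

The model fuses four branches:

* a five-level dilated 1-D convolution over the full protein sequence
  (padded 1024 × 40: amino-acid one-hot, 8-state secondary structure,
  11 physicochemical properties);
* two-head cross-attention `softmax(QKᵀ/√d_k)V` between the pocket sequence
  (64 × 40) and the ligand atom sequence (150 × 18), each direction convolved
  after attention;
* covalent 3-D encoders — an E(n)-invariant message-passing network over the
  pocket residue graph (5 Å contact edges) and an attentive fingerprint over
  the ligand bond graph (12-dim bond features);
* a heterogeneous complex graph over {protein atoms, ligand atoms,
  **3 environment nodes**} where the environment nodes carry 11 biochemical
  indicators (pI, GRAVY, net charge, H-bond donors/acceptors, aromatic
  rings, rotatable bonds, TPSA, logP) in a 3 × 5 matrix and connect to every
  atom with zero-distance edges; message passing runs three layers of three
  strictly ordered SAGE steps (environment→atoms, atoms↔atoms,
  atoms→environment), followed by distance-gated edge pooling.

A fusion MLP regresses the affinity; training is Adam on MSE (lr 1e-4,
plateau decay ×0.1, patience 10). Evaluation reports the five standard
metrics: Pearson R, RMSE, MAE, regression SD and concordance index.

Because no deep-learning framework exists in the supported R stack, the
package includes its own reverse-mode autodiff engine over dense matrices,
validated against finite differences in the test suite.

A fully synthetic complex generator with a planted linear affinity law
(contacts + H-bonding·polarity − rotatable bonds + noise) makes every stage
testable offline; it also writes PDB/SDF/index files so the real readers are
exercised end to end.

## Worked example

```r
library(bindgraph)

cfg  <- synth_config(n_complexes = 30, seed = 7)   # synthetic world
recs <- generate_dataset(cfg)

round(unlist(biochemical_indicators(recs[[1]], scale = FALSE)$ligand), 2)
#>  aromatic_ring_count rotatable_bond_count                 tpsa
#>                 0.00                 5.00                25.30
#>                 logp        formal_charge            hbd_count
#>                 4.27                 0.00                 0.00
#>            hba_count
#>                 0.00

round(unclass(assemble_env_nodes(biochemical_indicators(recs[[1]]))), 3)
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 0.322 0.471 0.438 0.170 0.247    # protein env: pI GRAVY charge HBD HBA
#> [2,] 0.000 0.333 0.126 0.618 0.000    # ligand env: rings rot TPSA logP -
#> [3,] 0.000 0.000 0.000 0.000 0.000    # shared env: ligand HBD HBA - - -

mcfg <- model_config(hidden_dim = 16L)
tcfg <- train_config(learning_rate = 1e-3, max_epochs = 10L, batch_size = 8L,
                     val_fraction = 0.2, seed = 1L)
fit  <- train_model(recs, mcfg, tcfg)
tail(fit$history, 3)
#>    epoch train_mse   val_mse    lr
#> 8      8  6.114363 2.5246798 0.001
#> 9      9  3.931031 0.6577952 0.001
#> 10    10  3.604660 0.6145166 0.001

set.seed(tcfg$seed)
vidx  <- sample(length(recs), 6L)
preds <- vapply(recs[vidx], predict_affinity, numeric(1),
                cfg = mcfg, params = fit$params)
labs  <- vapply(recs[vidx], `[[`, numeric(1), "affinity_label")
evaluate(labs, preds)
#> R = 0.8129  RMSE = 0.7839  MAE = 0.6846  SD = 0.6449  CI = 0.8000  (n = 6)
```

Ten epochs on 30 synthetic complexes already track the planted signal
(validation MSE falls from ~6 to 0.6; R ≈ 0.81 on the held-out complexes).
The acceptance suite trains longer on 200 complexes and requires mean
validation R ≥ 0.8 over three seeds.

## Command line

```sh
Rscript inst/cli/bindgraph simulate --out-dir data --n 200 --seed 1
Rscript inst/cli/bindgraph train    --dataset data --out-checkpoint model.rds \
        --hidden 16 --epochs 20 --lr 1e-3
Rscript inst/cli/bindgraph predict  --checkpoint model.rds --dataset data --out pred.csv
Rscript inst/cli/bindgraph evaluate --predictions pred.csv --labels data/INDEX.txt
```

Ablation switches (`--no-protein`, `--no-seq-complex`, `--no-covalent`,
`--no-noncovalent`, `--no-env-nodes`) remove entire modules, not just zero
them.

## Layout

* `R/autodiff.R`, `R/layers.R` — reverse-mode autodiff core and layers
* `R/chem.R` — molecule model, ring/aromaticity perception, TPSA, logP
* `R/io.R` — PDBbind index / pocket PDB / SDF / mol2 / prediction CSV
* `R/sequence_features.R`, `R/env_descriptors.R`, `R/graph_build.R` —
  featurization and the three graphs
* `R/model.R` — branch encoders, environment-HGT, fusion
* `R/train_eval.R` — Adam training, plateau decay, metrics
* `R/synthetic.R` — synthetic world and planted affinity law
* `R/cli.R`, `inst/cli/bindgraph` — command-line interface
* `vignettes/bindgraph-methods.Rmd` — model, assumptions, design choices
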