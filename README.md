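# nucsite

Residue-level prediction of RNA–small-molecule binding sites with a
multi-view graph convolutional network, in pure R.

RNA-targeted small molecules are a growing drug modality, and a central
computational step is deciding which nucleotides of an RNA 3D structure
form the ligand-binding pocket. `nucsite` frames this as binary
classification of every nucleotide: a residue is a **binding site** when at
least one of its atoms lies within 4 Å (inclusive) of any ligand heavy
atom, waters excluded.

## The model

Each RNA chain is one node set V (the nucleotides) carrying three edge
sets, one per structural **view**:

* **E_P** (primary): k = 13 nearest neighbours in sequence separation |i − j|;
* **E_S** (secondary): backbone adjacency plus annotated interactions
  (canonical/non-canonical pairs, base–ribose, base–phosphate);
* **E_T** (tertiary): k = 8 nearest neighbours in Euclidean distance
  between representative atoms (C4′, centroid fallback).

Node features X_init concatenate conservation (1 − H/H_max from the MSA
column entropy, H_max = log₂4), precomputed per-nucleotide embeddings,
one-hot bases, a five-column secondary block (degree + interaction flags),
five graph-topological descriptors (degree, neighbourhood connectivity,
normalized betweenness, clustering, eccentricity) and solvent
accessibility.

Each of three stacked layers propagates every view with a graph
convolution H_k = ReLU(Â_k X W_k), Â = D̃^{−1/2}(A + I)D̃^{−1/2}, and fuses
the three per-view vectors of each nucleotide with multi-head
self-attention over the views, X = LN(LN(H + Attn) + FFN(Attn)); the fused
matrix feeds the tertiary branch of the next layer while the primary and
secondary branches continue per-view. Per-layer MLPs give scale embeddings
Z_NA, Z_Loc, Z_Glob; projected raw features give Z_Node; self-attention
over the four scale tokens followed by average pooling gives Z_f, and an
MLP head outputs the binding probability (call = p ≥ 0.5). Training is
Adam at 6e-5, batches of 30 RNA graphs (block-diagonal), binary
cross-entropy, 200 epochs, best-validation-AUC checkpoint. Metrics are
precision, recall, MCC and rank-based AUC.

Because R has no deep-learning framework, the network runs on a compact
reverse-mode autodiff engine included in the package and checked against
finite differences in the tests. A synthetic-structure generator (nicked
circular duplex with a planted, geometrically verified ligand pocket)
makes every stage testable without downloads.

## Worked example

```r
library(nucsite)

# a synthetic RNA with a planted 5-residue pocket
sim <- simulate_structure(synthetic_spec(n_residues = 30, pocket_size = 5,
                                         seed = 3))
rec <- read_structure(sim$pdb_text, "A")
y   <- assign_labels(rec)                  # 4 A contact rule
which(y == 1) - 1                          # 0-based binding residues
#> [1]  1 15 27 28 29

# features and the three view graphs
coords <- representative_coords(rec)
gP <- build_primary_graph(30, 13); gT <- build_tertiary_graph(coords, 8)
gS <- build_secondary_graph(sim$annotation)
msa <- simulate_msa(sim$sequence, conserved_positions = 1:3, depth = 30,
                    seed = 3)
nfm <- assemble_features(
  one_hot   = one_hot_encode(strsplit(sim$sequence, "")[[1]]),
  secondary = secondary_feature_vector(sim$annotation),
  topological = topological_properties(gT$edges, 30),
  conservation = conservation_scores(msa), d_emb = 8)

# train on a simulated 40-RNA collection and evaluate held-out chains
ds  <- simulate_dataset(n_rnas = 40, signal = 2.0, seed = 7)
fit <- train_model(ds, train_config(epochs = 200, seed = 7),
                   model_opts = list(d_hidden = 32, n_heads = 2,
                                     d_scale = 32, clf_hidden = 32))
pr  <- predict_graphs(fit, ds$test)
compute_metrics(pr$y, pr$p)
#> TP 58  FP 7  TN 170  FN 18
#> precision 0.892  recall 0.763  MCC 0.759  AUC 0.967
```

The held-out AUC of 0.967 says the network recovers the planted 2-SD
feature signal almost perfectly; with `signal = 0` the same pipeline stays
at chance (AUC ≈ 0.55), confirming that structure alone leaks no label
information in the generator.

A command-line wrapper is installed at `exec/nucsite` with subcommands
`featurize`, `train`, `predict`, `evaluate`, `simulate`, `sweep`
(exit codes: 0 success, 2 input error, 3 numeric failure), e.g.

```sh
nucsite simulate --out data --n_rnas 40 --seed 7
nucsite train --data data --out run --epochs 200 --d_hidden 32
nucsite predict --checkpoint run/checkpoint.rds --data data --out pred.tsv
nucsite evaluate --predictions pred.tsv --out metrics.json
```

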