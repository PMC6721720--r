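# manlink

Link prediction on heterogeneous **molecular association networks** (MANs):
undirected graphs whose nodes are miRNAs, lncRNAs, proteins, drugs and
diseases, and whose edges are any of nine association types
(miRNA–disease, protein–protein, drug–protein, lncRNA–disease, ...). The
package is for computational biologists who want to score unobserved
molecule–molecule or molecule–disease pairs from the union of known
associations plus molecule-intrinsic data.

## Method

Every node is represented by the concatenation of two 64-dimensional
vectors:

* **attribute** — from what the molecule *is*: normalized 3-mer frequencies
  of ncRNA sequences over {A,C,G,U} (4³ = 64 dims), protein sequences after
  collapsing the 20 residues into four side-chain polarity classes,
  MeSH-style disease semantics (decayed DAG contributions
  `DD(t) = max Δ·DD(t′)`, Δ = 0.5, compared Jaccard-style:
  `S1(i,j) = Σ_{t∈N(i)∩N(j)} (D_i(t)+D_j(t)) / (DV(i)+DV(j))`), and Morgan
  (ECFP4) fingerprints of drug SMILES — each kind compressed to 64 dims by
  a rectifier autoencoder;
* **behavior** — from what the node *does* in the graph: a second-order
  LINE embedding minimizing
  `O2 = −Σ_{(i,j)∈E} w_ij · log p2(v_j|v_i)` with
  `p2(v_j|v_i) = exp(u′_jᵀ u_i) / Σ_k exp(u′_kᵀ u_i)`,
  trained by edge-sampling SGD with negative sampling (Rcpp).

Pairs are featureized by concatenating the two fused node vectors (256
features) and classified by a probability random forest; evaluation is
five-fold cross-validation in which per-fold embeddings see **training
edges only**, so held-out associations never leak into node
representations. Accuracy, sensitivity, specificity, precision, MCC, ROC
AUC and AUPR are reported per fold and as mean ± sd.

Because real MANs are aggregated from many external databases, the package
ships seeded generators (`gen_man_data()`) that emulate every raw input —
sequences, tree codes, SMILES, and a network with planted latent-factor
structure — so the whole pipeline is testable offline.

## Worked example

```r
library(manlink)

# synthetic study conditions: 200 nodes/kind, 500 edges/type, signal 0.9
bundle <- gen_man_data(synth_config(seed = 1))
bundle$network
#> Molecular association network
#>   nodes: 943 ( miRNA 189, lncRNA 195, protein 193, drug 174, disease 192 )
#>   edges: 4500 over 9 association type(s)

attrs <- encode_attributes(bundle$network, sequences = bundle$sequences,
                           smiles = bundle$smiles,
                           tree_codes = bundle$tree_codes, seed = 1)

cv <- cross_validate(bundle$network, attrs, k = 5, seed = 1)
cv
#> 5-fold cross-validation (both features, random_forest classifier)
#>           acc    sen   spec   prec    mcc    auc   aupr
#> fold 1 0.8056 0.7044 0.9067 0.8830 0.6240 0.8821 0.9035
#> ...
#> mean   0.7982 0.6978 0.8987 0.8733 0.6090 0.8787 0.9022
#> sd     0.0148 0.0261 0.0153 0.0168 0.0283 0.0118 0.0099
```

A mean AUC of 0.878 on the planted-signal network means the fused
attribute+behavior representation recovers most of the latent structure
that generated the edges; the attribute-only and behavior-only ablations
(`feature_mode = "attribute"` / `"behavior"`) score lower (0.824 / 0.844
under the same seed), showing the two channels are complementary.

To fit on the full network and rank candidate pairs:

```r
model <- man_fit(bundle$network, attrs, seed = 1)
mir <- subset(bundle$network$nodes, kind == "miRNA")$name[1]
dis <- subset(bundle$network$nodes, kind == "disease")$name
predict(model, data.frame(name_a = mir, kind_a = "miRNA",
                          name_b = dis, kind_b = "disease"), top_n = 5)
```

A command-line front end over the same functions lives at
`inst/cli/man-cli.R` (subcommands `synth`, `build`, `attrs`, `embed`,
`cv`, `predict`).

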