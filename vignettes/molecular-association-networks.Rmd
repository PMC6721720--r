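---
title: "Predicting molecular associations from node attributes and network behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting molecular associations from node attributes and network behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A molecular association network (MAN) is an undirected heterogeneous graph
over five node kinds — miRNA, lncRNA, protein, drug, disease — whose edges
are any of nine association types (miRNA–disease, protein–protein,
drug–protein, ...). Link prediction on this graph asks: given all known
associations, how plausible is an unobserved pair?

manlink represents every node by two complementary 64-dimensional vectors:

* **Attribute** — what the molecule *is*. miRNA/lncRNA sequences are encoded
  as normalized 3-mer frequencies over {A, C, G, U} (64 = 4³ dimensions);
  proteins the same way after collapsing the 20 amino acids to four
  side-chain polarity classes; diseases by their row of a pairwise semantic
  similarity matrix built from MeSH-style tree codes; drugs by a Morgan
  (ECFP, radius 2) fingerprint folded to 1024 bits. Each kind's raw matrix
  is compressed to 64 dimensions by a one-hidden-layer rectifier autoencoder
  trained to minimize mean squared reconstruction error.
* **Behavior** — what the node *does* in the graph. A second-order LINE
  embedding models the probability of observing context $v_j$ from vertex
  $v_i$ as $p_2(v_j \mid v_i) = \exp(\vec u_j'^{\,T} \vec u_i) / \sum_k
  \exp(\vec u_k'^{\,T} \vec u_i)$ and minimizes the degree-weighted KL fit
  $O_2 = -\sum_{(i,j) \in E} w_{ij} \log p_2(v_j \mid v_i)$, so nodes that
  share neighbors obtain similar vertex vectors even when not adjacent.

The fused 128-d node vectors are concatenated per pair (256 features, after
a canonical endpoint orientation) and a probability random forest classifies
pairs as associated or not, trained on all known associations plus an equal
number of uniformly sampled admissible non-edges.

## Disease semantics

Each tree code (e.g. `C04.557.465.625.600`) denotes the disease; removing
the final dot-separated segment yields the parent, and iterating gives the
ancestor DAG. The disease contributes 1 to itself; an ancestor $t$
contributes $DD(t) = \max_{t' \in \mathrm{children}(t)} \Delta \cdot DD(t')$
with decay $\Delta = 0.5$ (configurable), and $DV(D) = \sum_t DD(t)$. Two
diseases are compared Jaccard-style:
$S_1(i,j) = \sum_{t \in N(i) \cap N(j)} (D_i(t) + D_j(t)) / (DV(i) + DV(j))$.
Diseases with several tree codes get the union DAG with $DD = 1$ at every
own code; the max rule extends unchanged. Because no raw per-disease feature
other than this similarity is defined, a disease's attribute input is its
row of the $S_1$ matrix over the network's diseases, then compressed like
every other kind.

## Leak-safe cross-validation

`cross_validate()` partitions the edges into $k$ folds. Per fold, the
embedding is trained **only** on the training edges — a runtime assertion
verifies that the embedding input and the held-out positives are disjoint —
so test associations can never inform node representations. Nodes isolated
by the split receive the all-zero behavior vector, mimicking genuinely
unknown molecules. Attribute vectors are computed once, outside the folds:
they derive from sequences, tree codes and SMILES only, which contain no
association information. Training negatives are drawn outside *all* known
edges (so a held-out positive is never labelled negative during training)
and also outside the fold's test negatives; training sets are exactly
balanced. Two embedding scopes are supported: `all_edges` (embed every
training edge) and `exclude_target_type` (embed only the eight other
association types, for measuring how much the rest of the network alone
supports one target task).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent` (attributes) | 64 | attribute dimension after the autoencoder |
| `delta` | 0.5 | per-level semantic decay, in (0, 1) |
| `bits`, `radius` | 1024, 2 | fingerprint folding length and ECFP radius |
| `epochs`, `learning_rate` | 100, 1e-3 | autoencoder Adam training |
| `dim` (embedding) | 64 | behavior dimension |
| `negatives` | 5 | noise samples per positive in the SGD |
| `samples_per_edge` | 100 | SGD samples per directed edge |
| `rho0` | 0.025 | initial learning rate, linear decay to ~0 |
| `k` | 5 | cross-validation folds |
| `threshold` | 0.5 | classification cutoff for confusion metrics |

The SGD defaults (noise distribution proportional to out-degree^0.75,
K = 5, linear rate decay, alias-method edge draws) are the canonical
choices for this family of embedding methods; the embedding dimension 64 is
implied by the 128-d fusion. The autoencoder is a single encoder/decoder
pair of width 64 — the minimal architecture consistent with the rectifier
formulation — and all raw attribute inputs are nonnegative, which is why a
rectified decoder output can reconstruct them. The already-64-d 3-mer
vectors are passed through the autoencoder too (it serves normalization and
denoising, not only reshaping); `sae_for_kmer = FALSE` preserves the raw
vectors instead.

Two deliberate design choices that the underlying formulation leaves open:
pair features are the concatenation of the two fused node vectors under a
fixed kind-precedence orientation (Hadamard and average operators are
available via `operator=`), and behavior vectors are L2-normalized before
fusion — the magnitude of a trained vertex vector mostly tracks node
degree, while its direction carries the neighborhood information that
second-order proximity is about.

## The synthetic generator

Real MANs are aggregated from many curated databases that cannot ship with
a package. `gen_man_data()` instead plants a low-dimensional latent
structure: every node draws a factor vector $z \in \mathbb{R}^8$; each
association type places its edges among admissible pairs with probability
proportional to $s \cdot \mathrm{softplus}(\alpha\,(z_a^T z_b - 1.5\,
\mathrm{sd}))/\overline{\mathrm{softplus}} + (1 - s)$, with $\alpha = 4$.
The offset concentrates planted edges in the upper tail of the affinity
distribution; without it the near-linear softplus weighting spreads
positives so widely that even an oracle scoring pairs by the true latent
affinity cannot exceed AUC ≈ 0.82, leaving no headroom to demonstrate
learning. Sequences are coupled to the same factors by biasing their 3-mer
composition with a fixed random projection of $z$ (scaled by $s$), so the
attribute channel is informative as well. Tree codes and SMILES are
realistic in format (parent-closed code forests; valence-safe fragment
assemblies plus curated drug-like templates, all validated by parsing) but
deliberately carry no planted signal. At $s = 0$ every edge is uniform
noise and sequences are unbiased.

What passing tests on these data do and do not show: they demonstrate that
the pipeline recovers plantable structure through both channels, end to
end, leak-free; they do not certify performance on real aggregated
databases, whose degree distributions, identifier noise, and attribute
coverage gaps the generator does not emulate.

## The null and degree bias

A pure-noise network ($s = 0$) is *not* scored at AUC 0.5 by this — or the
original — evaluation protocol, and users should know why. Evaluation is
transductive: the same nodes appear in training and test pairs. Positives
are edges, so their endpoints are degree-biased draws, while uniformly
sampled negatives are not. Any node-identifying feature therefore lets the
classifier memorize per-node edge propensity: on an Erdős–Rényi null we
measure AUC ≈ 0.67 with pure random identity codes as features and ≈ 0.74
with the full pipeline, against ≈ 0.59 for a train-degree-only scorer.
This inflation is a property of uniform negative sampling in link
prediction generally; reported AUCs on real data include it. The package
keeps the conventional protocol (it is what the field reports) and exposes
`stratified_negatives` for a per-type-matched variant; degree-matched
negative sampling would remove the effect but changes the task definition.

## Numerical choices

* 3-mer windows containing symbols outside the alphabet are skipped, not
  the whole sequence; sequences with no valid window yield the zero vector.
* Softmax/log-softmax computations subtract the row maximum; the SGD
  sigmoid is clipped at |x| = 10.
* The autoencoder's decoder bias is initialized at the per-feature means,
  keeping the rectified output units in their active regime from the first
  step (a zero or small-constant start leaves a fraction of output units
  permanently dead and stalls reconstruction).
* The exact-softmax training mode (graphs ≤ 500 nodes) exists so the
  analytic gradient of $O_2$ can be verified against central finite
  differences; the SGD path is used everywhere else.
* All stochastic components (splits, negative draws, SGD, autoencoder,
  generators) are pure functions of one top-level integer seed;
  per-component seeds are derived arithmetically and the SGD uses a
  self-contained Mersenne Twister so results are bitwise reproducible.
* Canonical edge storage orients each undirected edge by the
  lexicographically smaller `(kind, name)` key; pair features instead use
  the kind-precedence order miRNA < lncRNA < protein < drug < disease.
* Unparseable SMILES raise an error in `smiles_to_fingerprint()`; the
  batch `fingerprint_matrix()` substitutes the zero fingerprint and counts
  the failures.

## Problem sizes

The study conditions used by the acceptance analyses are 200 nodes per
kind and 500 edges per association type (4500 associations, nine types,
signal 0.9), five folds, embedding dimension 64, 100 SGD samples per
directed edge. Unit tests exercise the same code paths on smaller networks.

## Known limitations

* Identifier unification across source databases is out of scope; names
  are opaque strings after trimming and case-folding.
* Only the second-order embedding objective is implemented; first-order
  proximity is not used by the prediction pipeline.
* AdaBoost is a discrete SAMME implementation over depth-1 stumps, kept
  deliberately plain; it is a comparison baseline, not the pipeline
  default.
* The disease attribute depends on which diseases are present in the
  network (it is a similarity *row*), so attribute vectors of diseases are
  not transferable between networks without re-encoding.
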