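---
title: "Subgraph-biased graph transformers for hERG cardiotoxicity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgraph-biased graph transformers for hERG cardiotoxicity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical and design choices made where the method left room.

## 1. The classification problem

Blockage of the hERG potassium channel is a proxy for drug-induced QT
prolongation. The observable is a channel-inhibition IC50 in micromolar;
the modeling task is binary: *blocker* versus *non-blocker*. Because IC50
is continuous, the class definition is itself a modeling decision, handled
by threshold schemes (Section 3).

## 2. Model

### 2.1 Molecular graphs

A molecule is parsed from SMILES with RDKit, reduced to its largest
fragment, stripped of stereochemistry, and renumbered into RDKit's
canonical atom ranking. Canonical ordering matters here more than in most
GNNs: the decision head flattens the latent atom matrix row-major, so atom
order reaches the classifier directly. With canonical ranking, every
spelling of a structure maps to the same input tensor and hence bitwise
the same prediction (this is tested).

Stereochemistry is deliberately discarded: the model's features and
subgraphs are constitutional, and the embedded scaffold reference tables
are stereo-free. Salt/mixture inputs are reduced to the largest fragment;
no other standardization is attempted.

Atom features (`feature_dim() = 19`): one-hot element over
{C, N, O, S, F, Cl, Br, I, P, other}, one-hot degree 0–5, aromatic flag,
in-ring flag, signed formal charge. The upstream description fixes only
"atomic properties", so this layout is a package decision, versioned with
the model archive. Graphs are zero-padded to `n_max = 45`; molecules with
45 or more heavy atoms are rejected at dataset load (the corpus filter
that keeps adjacency matrices sparse and small).

### 2.2 Predefined subgraphs

Four sub-adjacency matrices, in a fixed, documented order:

| kind            | atoms                         | edge rule |
|-----------------|-------------------------------|-----------|
| `all_atoms`     | all                           | all bonds (`= A`) |
| `murcko`        | ring systems + linkers        | induced (both ends inside) |
| `aromatic_rings`| aromatic atoms                | induced |
| `heteroatoms`   | N, O, S                       | **incident** (either end) |

The heteroatom slice uses incident edges by design: isolated heteroatoms
are rarely bonded to each other, so an induced subgraph over them would be
almost always empty and carry no message-passing signal. An incident
edge set keeps the bonds through which a heteroatom actually communicates.
The alternative (bare induced edges) was considered and rejected; it is
the one point where "sub-adjacency matrix" is interpreted rather than
literal. Slices carry no self-loops; the identity enters exactly once, in
the propagator normalization.

### 2.3 Meta-path attention and convolution

Per head `k`, raw weights `r^k ∈ R^T` are softmax-normalized to a
probability vector `w^k`, and `Q_k = Σ_i w_i^k G_i`. Softmax rather than
unconstrained weights for two reasons: attention shares are directly
interpretable (they are reported as pie-style shares), and nonnegative
`Q_k` guarantees the square-root degree normalization below stays
real-valued. The per-head meta-paths compose by ordered matrix product
`Q_p = Q_1 Q_2` (two heads by default; the product-over-heads reading of
the composition is used, consistent with its description as `Q_1 ⋯ Q_n`).

Products of symmetric matrices need not be symmetric, while molecular
graphs are undirected and the symmetric normalization presumes symmetry;
`Q_p` is therefore symmetrized, `S = (Q_p + Q_pᵀ)/2`, before
`P = D̂^{-1/2} (S + I) D̂^{-1/2}` with `D̂` the degree matrix of `S + I`.
Degrees are ≥ 1 by construction, so padded (isolated) nodes never divide
by zero; on the padded block `P` is the identity and zero features stay
zero, which is why training can run on unpadded `n_real`-sized matrices
and pad only the flattened vector — an exact optimization, not an
approximation.

Two convolution layers (widths 19 → 64 → 64, ReLU) propagate features over
`P`, which is computed once per forward pass and reused across layers (the
weights are trainable, so `P` changes between passes but not within one).
The 64-dim width matches the latent dimension used downstream as the
molecular fingerprint. The decision head flattens the `45 × 64` latent
matrix row-major and applies a 128-unit hidden layer and 2-way softmax.
Depth and widths of head and convolution are package decisions; the
upstream description fixes only the flatten scheme, the weight-shape
pattern and the final width 2.

### 2.4 Training

Cross-entropy, Adam (`lr = 1e-3`, β = 0.9/0.999), mini-batches of 64,
100 epochs, no early stopping. Every source of randomness — weight
initialization (Glorot uniform; the attention weights start near-uniform
with σ = 0.01 noise to break the symmetry between heads), batch shuffling,
class balancing — flows from one integer seed; the same seed reproduces
bit-identical parameters within a session. Backpropagation, including the
chain through the softmax weights, the matrix product of heads, the
symmetrization and the degree normalization, is hand-derived and verified
against central finite differences to ~1e-8 in the test suite.

Gradients and predictions go through BLAS; per-row results of a batched
matrix product can differ from the single-row computation in the last ulp,
so exact-reproducibility contracts (spelling invariance, archive reload)
are stated per molecule.

### 2.5 Interpretation and applicability domain

`subgraph_weight_shares()` reports softmax shares averaged over heads (and
fold models); `interpretation_matrices()` exports `G_i`, `Q_1`, `Q_2`,
`Q_p` exactly as used in the forward pass. The mean over real-atom rows of
the final convolution layer is the 64-dim molecular fingerprint (the
pooling is a package decision; padding rows are excluded by construction).
Leverage `h_i = x_i (XᵀX)^{-1} x_iᵀ` against the training fingerprint
matrix flags queries with `h > 3D/M` as extrapolations; a rank-deficient
`XᵀX` falls back to the Moore–Penrose pseudo-inverse and says so in the
report.

## 3. Threshold schemes

A scheme is `(active, inactive)` in µM: IC50 ≤ active → blocker,
IC50 > inactive → non-blocker, in between → removed as an ambiguous weak
blocker. Boundary semantics are "≤ / >": an IC50 exactly at the inactive
cutoff of a dual scheme is removed, which is the reading consistent with
the embedded 50-drug table (a 10 µM drug is undefined under `[1,10]`).
Named schemes: 1, 10, 20 (single); `[1,10]`, `[1,20]`, `[1,30]`, `[1,40]`
(dual). `[1,30]` is the recommended default — it also aligns with the
pharmacological 30-fold safety-margin convention. Balancing, when
requested, only subsamples the majority class uniformly under the seed;
nothing is oversampled or augmented.

## 4. Baselines

* **GTN**: the identical model restricted to the `all_atoms` slice. With
  one head the transformer stage collapses exactly to `Q_p = A` (softmax
  over one element is 1), which the tests assert — the subgraph bias is
  the only difference being measured.
* **MGCNN**: two graph-convolution layers on `A + I` with the same
  symmetric normalization, same atom features and widths as the
  transformer's convolution stage, plus per-layer batch normalization
  (batch statistics over all real-atom rows in the mini-batch; running
  means/variances with momentum 0.9 at inference) and the same
  flatten + MLP head. Only the propagator differs.
* **ECFP + SVM**: 1024-bit, diameter-4 circular fingerprints (Morgan
  radius 2) into an RBF SVM. The kernel is unspecified upstream, so its
  settings are package decisions: `gamma = 0.01` (squared Hamming
  distances between such fingerprints are of order tens, making the
  common `1/n_bits` default a nearly constant kernel) and `cost = 1`,
  binary features unscaled. Class probabilities are the decision margin
  through a logistic link rather than Platt fitting, which is unstable on
  small folds; the 0.5 cut then coincides with the decision boundary.

All four models expose one predict contract (per-molecule blocker
probability), so the evaluation layer treats them uniformly.

## 5. Evaluation

Accuracy, precision, recall and F1 from the confusion matrix with the
blocker class positive; zero-denominator metrics are reported as `NA`
with a warning, never as silent zeros, because zeros would distort fold
means. AUC is the rank (pairwise-concordance) statistic with ties counted
one half. Cross-validation is stratified — the corpus can be imbalanced up
to ~5:1, and unstratified folds would risk single-class test sets — with
per-fold class counts within one of proportionality; both fold-averaged
and fold-pooled summaries are emitted, labeled, since either convention is
defensible. Scheme comparisons use Welch's unequal-variance t-test on
fold-level metrics.

## 6. The synthetic generator

The generator exists so that every pipeline stage is testable without the
external bioactivity corpus. It emulates the corpus's *shape*: molecules
under 45 heavy atoms containing scaffolds, aromatic rings and N/O/S
heteroatoms; log10 IC50 values planted by a substructure rule with
Gaussian noise; and same-scaffold activity-cliff pairs.

Design: carbocyclic scaffold templates (benzene, naphthalene, indane,
cyclohexane variants) with one or two valence-safe attachment sites filled
from substituent pools; no ring-forming substitutions, so generation is
trivially valid. Heteroatoms enter only through the rule substituent pool,
which makes the default rule — potent (mean log10 IC50 = −1, i.e. 0.1 µM)
if any N/O/S atom is present, inert (mean 2, i.e. 100 µM) otherwise —
cleanly identified with a single substitution, and makes the heteroatom
subgraph the ground-truth attribution target. The rule predicate is
evaluated on the parsed molecule's subgraphs, not on hidden generator
state. Defaults: n = 1000 molecules, noise σ = 0.5 log units (so the
`[1,30]` band removes a realistic ambiguous fraction), 20% of molecules in
cliff pairs, 50/50 rule balance. An `aromatic` rule variant plants the
signal on ring presence instead.

What the generator does **not** emulate: real pharmacophore chemistry
(the rule is far simpler than hERG binding), assay noise structure,
scaffold diversity of a curated corpus, or class imbalance. Passing the
planted-rule tests therefore shows the architecture can learn and
attribute a subgraph-localized signal through the full pipeline — it does
not certify real-data performance, which depends on the external corpus.

## 7. Problem sizes and numerical conventions

Test and acceptance runs use sizes chosen to exercise the claims at desk
scale: the planted-rule benchmark at n = 1000 with a stratified 80/20
split and the default 100 epochs; attribution recovery over 5 seeds at
n = 400 and 50 epochs (attention shares move early in training); algebra
oracles on ≥ 100 random instances with n ≤ 8 nodes and T ≤ 4 slices at
tolerance 1e-8; spelling invariance over 100 molecules × 10 randomized
spellings. Model archives are JSON with 17 significant digits, which
round-trips doubles exactly; reloaded models reproduce bit-identical
predictions. Fixture tables are shipped as tab-separated text with the
printed SMILES stored verbatim (including typographic spaces, which the
parser strips).

## 8. Known limitations

- Chemistry requires a Python RDKit on PATH; there is no pure-R fallback.
- The external bioactivity corpus is not bundled; headline real-data
  metrics are out of desk-scale scope and are not asserted anywhere in
  the package.
- The model is constitutional: stereoisomers are indistinguishable by
  construction.
- Training is single-threaded CPU R; it is sized for corpora of a few
  thousand molecules, not for high-throughput screening libraries.
- Batch normalization makes MGCNN's training-mode forward depend on batch
  composition (standard for BN); inference uses running statistics and is
  deterministic.
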