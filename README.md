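# gstn — graph subgraph transformer networks for hERG blocker classification

Drugs that block the hERG potassium channel delay cardiac repolarization,
prolong the QT interval, and can trigger lethal arrhythmias; screening
candidate molecules for hERG liability is therefore a standard step in
preclinical drug discovery. This package implements a QSAR classifier for
that task aimed at computational chemists and cheminformaticians: given a
SMILES string, it predicts whether the molecule is a hERG **blocker**
(IC50 at or below an active threshold) or a **non-blocker** (IC50 above an
inactive threshold).

## The model

A molecule with `N` heavy atoms is a graph with adjacency matrix
`A ∈ R^{N×N}` and atom-feature matrix `X ∈ R^{N×D}`. Plain graph neural
networks treat this graph as homogeneous, which bounds their expressiveness
by the 1-Weisfeiler–Leman test and discards chemically meaningful
substructure. The graph *subgraph* transformer network (GSTN) restores that
heterogeneity with predefined subgraphs chosen for hERG pharmacology:

1. **Subgraph tensor.** `A` is decomposed into `T` sub-adjacency matrices
   `G_i` — the whole molecule, the Murcko scaffold (ring systems plus
   linkers), the aromatic rings, and the edges incident to N/O/S
   heteroatoms — stacked as `M = G_1 ⊕ … ⊕ G_T`.
2. **Meta-path attention.** Each attention head `k` carries learnable
   weights `w^k` (softmax-normalized over the `T` subgraphs) and forms the
   meta-path `Q_k = Σ_i w_i^k G_i`. The heads are composed by matrix
   product, `Q_p = Q_1 ⋯ Q_n` (`n = 2`), encoding n-hop relations between
   the weighted substructures.
3. **Graph convolution.** Two message-passing layers
   `X^{(l+1)} = σ( D̂^{-1/2} (Q̂_p) D̂^{-1/2} X^{(l)} W^{(l)} )` with
   `Q̂_p = Q_p + I` propagate atom features over the learned meta-graph
   into 64-dimensional latent atom vectors.
4. **Decision head.** The latent matrix is flattened row-major and passed
   through an MLP with a 2-way softmax (blocker / non-blocker),
   trained end-to-end with cross-entropy.

Around the model the package provides the full study pipeline:

- single and dual IC50 **thresholding schemes** (`[1,10]` … `[1,40]` µM;
  molecules between the cutoffs are ambiguous "weak blockers" and removed;
  `[1,30]` is the recommended default), with optional class balancing;
- **baselines** under one predict contract: the plain graph transformer
  (GTN, the model without predefined subgraphs), a two-layer molecular
  GCN with batch normalization (MGCNN), and ECFP4 fingerprints with an
  RBF-kernel SVM;
- **evaluation**: confusion-matrix metrics, rank-based ROC AUC, stratified
  k-fold cross-validation, Welch t-tests between schemes, and
  applicability-domain leverage `h_i = x_i (XᵀX)^{-1} x_iᵀ` with the
  `3D/M` extrapolation flag on the 64-dim latent fingerprints;
- **interpretability**: learned subgraph attention shares and per-molecule
  exports of `G_i`, `Q_1`, `Q_2`, `Q_p`;
- a **synthetic benchmark generator** (fragment grammar with planted
  substructure rules, log-normal activity noise, and same-scaffold
  activity-cliff pairs) so the whole pipeline is testable offline;
- embedded reference tables: 50 FDA-approved drugs with IC50 values and
  labels under all five schemes, and 81 activity-cliff case-study
  molecules with their Murcko scaffolds.

Chemistry (SMILES parsing, canonical atom ranking, scaffold extraction,
fingerprints) is delegated to RDKit through a bundled Python helper;
everything numerical — the meta-path algebra, hand-derived
backpropagation, Adam, the baselines — is implemented in base R and
verified against brute-force oracles and finite differences in the test
suite.

## Worked example

```r
library(gstn)

spec  <- synth_spec(n = 300, seed = 42)        # planted heteroatom rule
bench <- make_benchmark(spec)
ds    <- build_dataset(bench$records, scheme = "1-30")
dataset_summary(ds)
#>   scheme blocker non_blocker total undefined_removed size_filtered
#> 1 [1,30]     147         125   272                28             0

fold <- stratified_kfold(ds$records$label, k = 5, seed = 42)
fit  <- gstn(ds$records[fold != 1, ], epochs = 60, seed = 42)
summary(fit)
#> Graph subgraph transformer network
#>   subgraphs (T = 4): all_atoms, murcko, aromatic_rings, heteroatoms
#>   heads: 2, conv layers: 2 (latent 64), MLP hidden: 128
#>   trained on 217 molecules, 60 epochs; final loss 0.0005902
#>   subgraph attention shares (mean over heads):
#>      all_atoms         murcko aromatic_rings    heteroatoms
#>         0.2323         0.2335         0.2469         0.2873

test <- ds$records[fold == 1, ]
p    <- predict(fit, test$smiles)
m    <- classification_metrics(
  confusion(test$label, ifelse(p >= 0.5, "blocker", "non_blocker")))
sprintf("held-out accuracy %.3f, AUC %.3f", m$accuracy,
        roc_auc(test$label, p))
#> [1] "held-out accuracy 1.000, AUC 1.000"

leverage(latent_features(fit, ds$records$smiles[fold != 1]),
         latent_features(fit, test$smiles))
#> <leverage> 55 queries vs M = 217, D = 64; threshold 3D/M = 0.8848
#>   flagged outside the applicability domain: 2
```

The dataset summary shows the dual threshold at work: 28 of 300 molecules
fall between 1 and 30 µM and are removed as ambiguous. The attention
shares show the model assigning the largest share to the heteroatom
subgraph — the substructure that actually drives the planted rule — and
the held-out metrics confirm the rule is learned. The leverage report
flags 2 of 55 held-out molecules as requiring extrapolation beyond the
training set's latent chemical space.

A command-line surface over the same functions (label / train / crossval /
predict / interpret / ad / synth) ships at `inst/cli/hergst.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hergst.R",package="gstn"))')" \
    label --input activity.tsv --scheme 1-30
```

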