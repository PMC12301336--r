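# drugsyn

Multimodal prediction of synergistic drug combinations in cancer cell
lines.

## What it does

Given a *drug pair-cell line* triplet — two SMILES strings and the cell
line's landmark-gene expression profile — `drugsyn` classifies the
combination as synergistic or antagonistic under the Loewe additivity
reference. It fuses two feature views of every triplet and trains the
whole network end-to-end:

* **1D view:** a 768-d chemical-language vector per drug (pluggable
  backend with a deterministic hashed-substructure fallback) plus a 256-d
  compression of the cell line's expression through a three-layer MLP
  (978 -> 768 -> 512 -> 256).
* **2D view:** a two-layer graph convolutional network,
  `h^(l+1) = ReLU( D^-1/2 (A + I) D^-1/2  h^(l) W^(l) )`,
  over each drug's molecular graph (78-d atom features, widths
  78 -> 512 -> 128); node2vec embeddings (128-d) of a protein-protein
  interaction network over the same genes; and a *graph-trans pooling*
  block in which the drug atoms and protein nodes form one token set
  passed through two transformer encoder layers with 2-head scaled
  dot-product attention, `softmax(Q K' / sqrt(d_k)) V`, then mean-pooled
  into a 256-d feature.

The concatenated 2048-d feature feeds a softmax MLP (512 -> 128 -> 32 ->
2) trained with Adam (learning rate 5e-4, dropout 0.3) on cross-entropy.
The attention score matrices double as the interpretability layer:
per-triplet drug-atom x gene and atom x atom heatmaps, and ranked gene
lists.

The package also ships the full experimental protocol around the model:
Loewe-score preprocessing (replicate averaging, strict >10 / <0
labelling), random k-fold and four leave-group-out cross-validation
schemes (combination, drug, cell line, tissue), an eight-metric panel
(AUROC, AUPR, ACC, BACC, PREC, TPR, KAPPA, F1), and a synthetic-data
generator with a planted decision rule so everything runs and is tested
fully offline.

## Worked example

Train on a synthetic study whose labels follow a planted rule — *both
drugs aromatic XOR the cell line carries an expression signature* — with
10% label noise, then evaluate and inspect attention:

```r
library(drugsyn)

fx  <- make_fixture_dataset(fixture_config(seed = 0))   # 2000 triplets
emb <- embed_network(fx$ppi, walk_config(seed = 0))     # node2vec, frozen
P   <- align_embedding(emb, setdiff(names(fx$expression), "cell_line"))

fit <- train_model(fx$triplets, fx$expression, P,
                   study_model_config(variant = "full", seed = 0),
                   quiet = TRUE)
predict(fit, fx$triplets[1:3, ])[, c("drug_a", "drug_b", "cell_line",
                                     "label", "prob_synergy", "pred")]
```

```
# A tibble: 3 x 6
  drug_a drug_b cell_line label prob_synergy  pred
  <chr>  <chr>  <chr>     <int>        <dbl> <int>
1 D04    D09    CL09          0       0.117      0
2 D15    D18    CL14          1       0.934      1
3 D19    D20    CL07          0       0.0847     0
```

Five-fold cross-validation with the metric panel:

```r
plan <- make_random_kfold(fx$triplets, k = 5, seed = 0)
cv   <- run_cross_validation(fx$triplets, fx$expression, P, plan,
                             study_model_config(variant = "full", seed = 0))
cv
```

```
<drugsyn_cv> scheme=random_kfold, 5 folds, variant=full
  auroc 0.909 +/- 0.008
  aupr  0.896 +/- 0.018
  acc   0.904 +/- 0.010
  bacc  0.904 +/- 0.010
  prec  0.909 +/- 0.023
  tpr   0.900 +/- 0.016
  kappa 0.807 +/- 0.020
  f1    0.904 +/- 0.006
```

The cross-validated AUROC sits at
`planted_rule_ceiling(0.1) = 0.9`, the information-theoretic expectation
under 10% label flips (finite-sample noise allows small excursions above
it), so the network recovers essentially all of the planted structure. Attention interpretability for one triplet:

```r
recs <- attention_scores(fit, fx$triplets[1, ])
v    <- slice_attention(recs, "atomA", "gene")  # final layer, heads averaged
top_attended_genes(v, k = 3)                    # genes this drug attends to
autoplot(normalize_view(v))                     # column-normalized heatmap
```

```
# A tibble: 3 x 2
  gene  score
  <chr> <dbl>
1 G0050 1
2 G0010 0.877
3 G0020 0.777
```

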