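---
title: "Multimodal synergy prediction: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal synergy prediction: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two drugs given together can act more strongly than the sum of their
individual dose–response effects (synergy, under the Loewe additivity
reference) or more weakly (antagonism). Screening all pairs experimentally
is infeasible, so `drugsyn` learns a binary classifier over *drug pair ×
cancer cell line* triplets: given the SMILES of both drugs and the cell
line's landmark-gene expression profile, predict synergistic (1) versus
antagonistic (0).

## Preprocessing and labels

Raw screens report a Loewe synergy score per (pair, cell line) record.
`average_duplicates()` collapses replicate measurements of the same
unordered pair to their arithmetic mean *before* labelling;
`label_by_threshold()` then labels scores strictly above 10 as synergistic
and strictly below 0 as antagonistic, and drops the ambiguous band
`[0, 10]`. Boundary scores of exactly 10 or 0 are dropped because both
inequalities are strict; averaging runs first so replicate noise cannot
push a record across a threshold twice.

Drug-pair identity is unordered throughout. Each triplet is stored once;
symmetry is restored at prediction time (below).

## The two feature views

**1D view (sequence-level).** Each drug's SMILES is embedded as a 768-d
vector by a chemical-language backend. The backend is an *interface*: a
pretrained transformer chemistry model can be plugged in via
`chem_backend("pretrained", embed_fun = ...)`, while the default
`hashed_fallback` computes a deterministic 768-d descriptor offline —
circular (Morgan-style, radius 2) substructure identifiers feature-hashed
into 768 signed buckets and L2-normalized. The fallback keeps the whole
package testable with no model download; it is a descriptor, not a learned
embedding, and we make no claim that it matches a pretrained model's
quality. The cell line's expression vector (978 landmark genes in
full-shape runs; configurable) is z-scored per gene over the *training*
cell lines and compressed by a three-layer MLP, 978 → 768 → 512 → 256 with
ReLU after the first two layers and dropout during training. Only the
depth (three layers) and the 256-d output are structural commitments of
the architecture; the intermediate widths 768/512 are a gentle geometric
taper.
The 1D feature is the concatenation (drug A, drug B, cell line), 1792-d.

**2D view (structure-level).** Each drug becomes a heavy-atom molecular
graph with 78-d atom features: element one-hot (44 symbols with an "other"
bucket), degree, attached-H count, and implicit valence one-hots over
0..10, plus an aromaticity flag — the featurization convention of the
molecular-GCN lineage this model belongs to. A two-layer GCN,
\(h^{(l+1)} = \mathrm{ReLU}(\hat A\, h^{(l)} W^{(l)})\) with widths
78 → 512 → 128, produces one 128-d embedding per atom. We add self-loops
in the renormalized propagation matrix
\(\hat A = \tilde D^{-1/2}(A+I)\tilde D^{-1/2}\); without them a node
discards its own features. `normalize_adjacency(..., add_self_loops =
FALSE)` reproduces the literal unaugmented form. Bond orders are not used:
the propagation consumes binary adjacency only.

The protein–protein interaction network over the same gene panel is
embedded by node2vec: second-order biased random walks (return parameter
`p`, in–out parameter `q`) followed by skip-gram with negative sampling.
The embeddings are computed once and **frozen** during model training —
they are inputs, not trainable parameters. Defaults `p = q = 1`,
10 walks per node of length 80, window 10, 128 dimensions — the standard
node2vec operating point. PPI edges are unweighted; genes present in the
expression panel but absent from the network receive zero vectors with a
warning.

**Graph-trans pooling.** For a triplet, the drug-A atoms, drug-B atoms,
and all gene vectors are stacked into one token matrix (width 128) and
passed through two transformer encoder layers. Each layer is post-norm:
`LayerNorm(X + MHA(X))` then `LayerNorm(y + FFN(y))` with
`FFN(y) = ReLU(y W1 + b1) W2 + b2`. Multi-head attention uses 2 heads of
width \(d_k = 32\) (the tuned "hidden size 64" split across heads), and
the FFN inner width is also 64. A two-layer feed-forward with no
activation between the layers would collapse to a single linear map, so
ReLU — the module-wide activation — sits between them. There is
**no positional encoding**: the tokens are a set (atoms and proteins), so
the pooled representation is invariant to token permutation — a property
the test suite asserts to 1e-5. After the encoder stack, tokens are
mean-pooled and a fully connected ReLU layer produces the 256-d 2D
feature; 256 is chosen so the 2D part balances the 1792-d 1D part at
fusion. Dropout 0.3 is applied to the attention and FFN
sublayer outputs during training.

## Classifier and training

The fused feature (2048-d for the full model) feeds a softmax MLP with
hidden widths 512 → 128 → 32 (the 512- and 32-wide layers are the ones
whose activations the interpretability module projects; 128 interpolates
between them) and a 2-class linear output. Training minimizes mean
cross-entropy with Adam at learning rate 5e-4, dropout 0.3, batch size
128. We reduce the loss by the batch mean rather than a sum so the
learning rate is independent of batch size. All active branches — GCN,
encoder stack, pooling projection, cell-line MLP, classifier — train
jointly by backpropagation; the chemical-language drug vectors and the
node2vec table stay frozen. Gradients are hand-derived; a test compares
them against central-difference numeric gradients at 1e-4 relative
tolerance.

Batches are *pair-blocked*: rows sharing an unordered drug pair are kept
adjacent so each pair's token matrix is encoded once per batch, and each
unique drug's GCN pass and each cell line's MLP pass are likewise shared.
This is exact, not an approximation — the shared computation is a single
node in the computation graph whose gradient accumulates over the rows
that consume it. Only the shuffling unit changes (pairs instead of rows).

**Drug-order symmetry.** The stored pair order is arbitrary, so training
randomly swaps drug order per example per epoch (`augment = TRUE`), and
prediction averages the forward passes of both orders. The 2D branch is
already order-invariant (token permutation); the averaging makes the 1D
branch symmetric too, giving `predict(A,B,c) = predict(B,A,c)` exactly.

Early stopping monitors the loss on a 10% validation split with patience
10 (defaults); the epoch budget, batch size, and early-stopping rule are
optimization choices of this package, not constraints of the
architecture. Seeds control weight
initialization, shuffling, dropout, and the walk/skip-gram sampling;
single-threaded runs are bitwise reproducible (floating-point reduction
order makes multi-threaded BLAS reproducibility best-effort only).

## Evaluation

`compute_metrics()` reports AUROC (rank statistic, ties counted ½), AUPR
(step-wise precision–recall integration, i.e. average precision — not
trapezoidal), accuracy, balanced accuracy `(TPR + TNR)/2`, precision, TPR,
Cohen's kappa `(p_o − p_e)/(1 − p_e)`, and F1, with thresholded metrics at
the natural 0.5 cut (exposed as a flag rather than optimized). Single-class truth yields `NA` rank metrics with an explicit
flag rather than a silent 0. Cross-validation retrains from scratch per
fold and summarises mean ± sample (n−1) standard deviation.

Four leave-group-out schemes hold out entire drug combinations, drugs,
cell lines, or tissues; the splitter re-verifies by exhaustive scan that
no held-out group member appears in training. Group frequency ranking
breaks ties lexicographically for reproducibility, and the cell-line →
tissue map is an explicit two-column input because no canonical map
exists for synthetic or arbitrary panels.

## Interpretability

Attention records (one score matrix per layer × head, rows summing to 1)
are exported with a role index mapping each token to drug-A atom, drug-B
atom, or gene. Views slice the matrix to drug-atoms × genes or atom ×
atom; the default reporting convention is the **final layer with heads
averaged**, with per-head export available; the layer/head choice is a
reporting convention, not part of the model. Min–max column normalization is
applied to the *sliced* matrix (the heatmap's scope). For ranking genes by
the attention a drug directs at them, aggregation is max-over-atoms on the
raw slice — per-column min–max first would force every non-constant
column's maximum to exactly 1 and erase the ranking — and the aggregate is
then scaled to [0, 1] across genes.

Hidden-embedding projection uses a seeded principal-component projection
to 2D as the package's default method (the `method` argument leaves room
for manifold alternatives), with component signs fixed deterministically.

## The synthetic study

All tests run offline on data from `make_fixture_dataset()`:

* **Molecules** — drawn from a curated library of 60 valid drug-like
  SMILES, about half containing an aromatic ring and half purely
  aliphatic.
* **PPI network** — preferential attachment with `m = 2` edges per node:
  exactly `(n − m)·m` edges, connected, right-skewed degrees, emulating
  the scale-free shape of real interactomes.
* **Expression** — standard normal per gene, plus a +2 shift on a 10-gene
  signature set for a random half of the cell lines.
* **Labels** — the planted rule `label = [both drugs aromatic] XOR [cell
  line carries the signature]`, sampled stratified so the class balance
  stays near 50%, then flipped independently with probability ε. Synthetic
  Loewe-style scores consistent with the labels are attached so fixtures
  also exercise the thresholding pipeline.

The XOR couples a structural drug property to an expression property, so
no function of the drugs alone (e.g. the whole 2D branch, which by
construction never sees the cell line) can beat chance. With flip noise ε
the best achievable AUROC against the noisy labels is `1 − ε`
(`planted_rule_ceiling()`): the optimal scorer is the rule itself, correct
pairs contribute `(1−ε)²` and ties half of `2ε(1−ε)`.

Study scale: 20 drugs, 15 cell lines, a 60-gene panel, and 2,000 triplets
at ε = 0.1 — a proportional scale-down of the real screening corpus this
family of models trains on (38 drugs × 31 cell lines ≈ 23k usable
triplets), keeping several triplets per drug pair so the pair-blocked
batching is representative. `study_model_config()` fixes the optimization
budget for this study at up to 20 epochs with early-stopping patience 4,
which the convergence traces show is ample at this sample size. On this
study the full fusion model reaches the noise ceiling to within a few
hundredths of AUROC; the 2D-only variants sit at chance (they cannot see
the cell line), and the cross-validated comparison of full versus
single-view ablations mirrors, qualitatively, the fusion advantage the
architecture was designed around. What passing these tests shows is that
the implementation learns exactly the planted structure; it does not show
real-data performance, where labels are noisier, chemistry is more
diverse, and expression signatures are not clean two-level shifts.

## Numerical choices and degenerate inputs

* Softmax and cross-entropy are log-sum-exp stabilized; probabilities are
  floored at 1e-12 before logarithms; attention logits are checked finite
  and non-finite values raise an error instead of propagating NaN.
* LayerNorm uses ε = 1e-5; weights initialize Glorot-uniform; biases and
  LayerNorm offsets start at zero.
* Zero-degree nodes under `add_self_loops = FALSE` keep zero rows in
  \(\hat A\); single-atom molecules collapse the GCN to a plain MLP.
* Single heavy atoms and bondless ions are parsed by a dedicated V2000
  fallback because the general SDF reader requires a bond block.
* Constant attention columns min–max-normalize to zero (logged note).
* Expression z-scoring floors near-zero gene standard deviations at 1 to
  avoid division blow-ups on constant genes.
* Frequency ties in group ranking and score ties in gene ranking break
  lexicographically for reproducibility.
* The biased-walk, skip-gram, and encoder-layer kernels are compiled
  (Rcpp/RcppArmadillo) and draw from R's RNG, so seeded runs remain
  reproducible; the linear algebra goes through the same BLAS as base R.

## Known limitations

* The hashed chemical descriptor is a stand-in interface for a pretrained
  chemical-language model, adequate for structure-sensitivity but not a
  substitute for learned chemistry.
* Aromaticity perception follows OpenBabel/ChemmineR ring analysis;
  exotic tautomers may be flagged differently than by other toolkits.
* Bond types, chirality, and 3D conformations are not encoded (binary
  adjacency only), matching the architecture's design.
* The dense T ≈ 1,000-token attention (978 genes + atoms) is within
  desk scale but quadratic in tokens; very large gene panels would need
  sparse attention, which is out of scope.
* Multi-fragment SMILES (salts) are kept whole as disconnected graphs
  rather than reduced to the largest fragment.
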