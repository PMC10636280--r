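---
title: "Multilayer graph neural networks for gene classification: models, attribution, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer graph neural networks for gene classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Predicting whether a gene is disease-associated (the motivating case:
cancer gene versus non-cancer gene) from (i) per-gene multi-omics feature
vectors and (ii) gene–gene interaction networks is a node-classification
problem. A single interaction network is an incomplete, noisy snapshot of
gene relationships, and models trained on different networks can disagree
sharply on the same gene. This package classifies genes by learning from
**several networks jointly**, and then explains each prediction at two
levels: which input features mattered, and which network mattered.

## Model

Let there be $K$ undirected networks ("layers") over a shared gene universe
of size $N$, and a feature matrix $X \in \mathbb{R}^{N \times d}$. Genes may
be absent from some layers ($N_i \le N$).

1. **Shared per-layer GNN $f_1$.** A GNN (GCN by default, GAT optionally)
   with 3 message-passing layers of width 64 runs independently on every
   layer graph with *shared* parameters, producing a state for every
   (gene, layer) instance. GCN aggregation is
   $h_u' = W^\top \sum_{v \in N(u) \cup \{u\}} h_v / \sqrt{\hat d_v \hat d_u}$
   with $\hat d_i = 1 + |N(i)|$; GAT uses softmax attention over the closed
   neighborhood with LeakyReLU-scored logits. Because $f_1$ is shared, the
   trainable parameter count does not depend on $K$.
2. **Meta-GNN $f_2$.** Every gene gets a *meta-node*, connected by one
   *meta-edge* to each of its layer instances (its "star graph"). The
   meta-node state is initialized from the gene's raw features through a
   learned linear projection $d \to 64$ (see Design choices), and one GNN
   layer (width 64, shared across genes) exchanges messages over the star.
   Meta-edges carry continuous weights (1 in normal operation) that scale
   messages across the edge — the hook used by edge attribution.
3. **Classifier $f_3$.** A one-hidden-layer MLP with a two-class softmax
   maps the meta-node state to $\hat y_j \in [0,1]$, the positive-class
   probability.

Training minimizes cross-entropy over the training genes' meta-node outputs
with Adam (learning rate $10^{-3}$), dropout on hidden states, and weight
decay on weight matrices. The reference protocol trains 2000 epochs; the
checkpoint with the best validation AUPRC (evaluated every 10 epochs) is
returned alongside the final one.

There is no GPU framework underneath: the forward pass, reverse-mode
gradients (with respect to parameters, input features, and meta-edge
weights) and the Adam loop are implemented directly in R on sparse
matrices, and are verified in the test suite against central-difference
numerical gradients and a dense normalized-adjacency oracle.

## Split protocol

Evaluation follows the multilayer protocol: the labeled genes of one
designated *test layer* are split 75%/25% with per-class (stratified)
sampling; the 25% part is the held-out test set. All remaining labeled
genes from any layer are split 90%/10% into train/validation. The test set
is a function of `(test_layer, seed)` only, so it is bit-identical as more
layers are added — the property that makes AUPRC comparable across $K$.

## Attribution

Both explainers are integrated gradients (IG) with the straight-line path
approximated by a midpoint Riemann sum (default 128 steps; the midpoint
rule is exact for linear models at any step count and converges as
$O(\text{steps}^{-2})$ for completeness).

* **Node features** (edges fixed): baseline is the all-zero feature matrix.
  Attributions are reported for every gene in the target's $k$-hop
  receptive field, $k$ = number of $f_1$ layers, plus the target's own
  meta-node input (the projection path). The completeness axiom
  ($\sum$ attributions $= F(x) - F(0)$) is asserted in the tests at 1%
  relative error.
* **Meta-edges** (features fixed): all meta-edge weights are interpolated
  jointly from 0 to 1; the per-edge attribution is the averaged gradient.
  Per meta-node, values are min–max scaled to $[0,1]$, so the most
  important layer always scores exactly 1 (a single meta-edge scores 1
  when nonzero). For all-positive attributions with a near-zero minimum
  this coincides with dividing by the maximum value. Min–max was chosen
  over "divide by max |value| and clip negatives" because raw meta-edge
  attributions are frequently *all negative* on feature-dominated
  predictions (cutting every meta-edge can raise an already saturated
  probability), and clipping then collapses the statistic to all-zeros and
  erases the relative layer ordering, which min–max preserves. The raw
  signed attributions are always reported alongside. For GCN convolutions
  an exact star-local fast path is used ($f_1$ outputs do not depend on
  meta-edge weights), verified to machine precision against the
  whole-graph path.

Neighbor importance aggregates a feature-attribution matrix to one number
per neighboring gene: the **signed** maximum over features (an
`absolute = TRUE` variant exists; the signed default ranks purely
inhibitory neighbors low). Zero rows are excluded, ties break
lexicographically.

## Downstream statistics

* **Cancer-neighbor fraction**: positively labeled neighbors / degree, per
  gene per layer.
* **Variance/correlation analysis**: per gene, the SD of meta-edge
  importance across layers and the Pearson correlation between importance
  and neighbor fraction; genes stratified at the median SD, mean
  correlation per group. The expected signature — higher correlation in the
  high-variance group — says network importance tracks the cancer
  neighborhood exactly where importance varies.
* **One-way ANOVA** across layers of meta-edge importances (fixed effects);
  type-I calibration under the null is asserted at $0.05 \pm 0.03$ over 200
  simulations.
* **Preranked GSEA**: classic weighted Kolmogorov–Smirnov running sum
  (weight exponent $p=1$; hits increment $\propto |r|^p$, misses decrement
  $1/(N-N_h)$), significance by gene-label permutation on the fixed ranking
  (one-sided in the observed direction, $(1+\text{exceed})/(1+n_{perm})$,
  per-set seed = seed + set index), BH-FDR across sets, size filters
  5–500. This is implemented in-package so the pipeline is self-contained;
  tail details will differ from external GSEA tools.

## Synthetic benchmark: what it emulates and what it does not

`benchmark_spec()` defines a seeded world with the *shape* of the real
data: `n_genes = 600`, `n_layers = 3`, `d_features = 64` (the real setting
is 16 cancer types × 4 omics), genes missing from layers at rate 0.1 (each
gene kept in ≥1 layer), labeled fraction 0.7, and positive prevalence 0.103
(mirroring 887 positive / 7753 negative labeled genes). Signal is planted
two ways: `informative_features = 8` columns are shifted by one noise SD for
positives, and the informative layer(s) wire positive–positive pairs with
probability `edge_density + 0.2 * homophily` (0.17 at the defaults versus
0.01 background). `labeled_fraction` is an addition to the stated field
list: the discovery workflow needs unlabeled genes to rank.

The generator does **not** reproduce scale-free degree distributions,
correlated omics features, or label noise. A green test on this world
establishes that the machinery recovers planted signal of the stated kind
and strength — not that the model would attain any particular accuracy on
real interaction networks.

## Numerical and design choices

* **Meta-node initialization**: raw features must meet $f_1$ outputs (width
  64) inside $f_2$; a learned projection reconciles the dimensions. The
  alternative (a dimension-matched first $f_2$ layer consuming raw
  features directly) is equivalent in expressive power.
* **Stars are undirected** for $f_2$; only the meta-node's output feeds
  $f_3$. ReLU after every $f_1$ layer and every $f_2$ layer except the
  last; no residual connections or batch norm.
* $f_3$ has one hidden layer (width = $f_2$ width) and a 2-class softmax;
  $\hat y$ is the positive-class probability.
* **Defaults left open by the protocol**: dropout 0.5, weight decay 5e-4,
  validation every 10 epochs with best-validation checkpointing; all
  exposed in `model_config()`/`train_emgnn()`.
* **AUPRC** is average precision with tied scores grouped (constant scores
  give the prevalence); no interpolation.
* **Majority-vote ties** resolve to the positive class (recall-favoring for
  screening; an even split is possible with an even number of networks).
* **Edge confidence filtering** keeps edges with score ≥ threshold and then
  drops degree-0 nodes; without filtering, isolated nodes are representable
  in edge lists as self-loop lines (`g<TAB>g`), which the loader converts
  back — self-loops are never stored as edges.
* **Determinism**: every stochastic step (init, dropout, splits, generator,
  permutations, ablations) flows from explicit integer seeds; edge-removal
  ablations derive per-layer seeds as `seed + layer index` so results do
  not depend on layer order.
* **Epoch scaling in tests**: the acceptance-world fits use 150 epochs
  (validation AUPRC plateaus by ~120 there); module-level property tests
  use 60–80 epochs on smaller worlds. These are runtime choices, not tuned
  thresholds; the API default remains 2000.

## Known limitations

* GAT training is supported but slower than GCN (edge-wise attention in
  plain R); GCN is the default and the better performer in the reference
  setting.
* Meta-edge IG for GAT uses the whole-graph path rather than the star-local
  fast path.
* The CLI reads JSON (not YAML) configuration files, as no YAML parser is
  available in the target environment.
* Checkpoints store plain-text JSON; for very large models a binary format
  would be preferable.
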