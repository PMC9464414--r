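---
title: "Predicting protein-protein interaction from structure with a mutual graph attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interaction from structure with a mutual graph attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Most machine-learning predictors of protein-protein interaction (PPI) work
from amino-acid sequence. This package instead classifies pairs of *folded
structures*: the only input per protein is the set of 3D atom positions in a
PDB file. That makes the method indifferent to whether the object is a
protein at all — anything that can be coarse-grained into labelled points in
space can, in principle, be fed through the same pipeline.

The pipeline has four stages.

**1. Contact graph.** Each residue is collapsed to the unweighted centroid of
its heavy atoms (`parse_pdb()` + `coarse_grain()`). Two residues are joined
by an edge when their centroids lie strictly closer than a threshold,
9.5 Å by default — wide enough that a typical globule's contact graph is
connected, narrow enough that the graph stays sparse (`build_graph()`).
Distances are computed on centroids only, and the edge set is by construction
invariant under rigid motions of the structure.

**2. Vertex embedding.** A vertex is described by its 1-neighborhood
subgraph key: its own residue label plus the sorted multiset of its
neighbors' labels (`subgraph_key()`). A dictionary of keys is collected over
the training graphs and each key is assigned a *fixed* random unit-norm
vector in $\mathbb{R}^d$ ($d = 20$ by default; `build_vocabulary()`,
`embed_vertices()`). The vectors are not trained. Each key's vector is a
deterministic function of the vocabulary seed and the key itself, which has
two consequences: the dictionary's content does not depend on the order in
which graphs are scanned, and a novel key on a held-out protein embeds
through exactly the same mechanism (a hash-seeded unit-norm draw) instead of
needing an out-of-vocabulary special case.

**3. Weight-shared GCN and mutual attention.** With
$\tilde A = \hat D^{-1/2}(A + I)\hat D^{-1/2}$ the symmetrically normalized
adjacency, an $l$-layer graph convolutional network updates
$X_{t+1} = \mathrm{ReLU}(\tilde A X_t W_t)$, with the same weights $W_t$
applied to both proteins of a pair. The final embeddings $h^{(1)}, h^{(2)}$
are coupled through mutual attention
$\alpha_{ij} = w^\top \tanh(U h_i^{(1)} + V h_j^{(2)})$, averaged over the
partner protein into per-residue scores, and softmaxed into probability
vectors $p^{(1)}, p^{(2)}$. Context vectors $s^{(m)} = \sum_i p_i^{(m)}
h_i^{(m)}$ compress each protein, whatever its size, into $d$ numbers
(`gcn_forward()`, `attention_scores()`, `knowledge_select()`).

**4. Classifier.** The concatenated context vectors pass through one affine
map to two logits and a softmax (`classify()`). The class-1 probability is
the predicted probability that the two proteins interact. The probability
vectors $p^{(m)}$ are kept: residues holding a large share of $p$ are the
model's (unsupervised) candidates for interaction-relevant residues
(`importance_profile()`).

## Design choices where the architecture was open

* **Classifier head.** "Single-layer feed-forward network" is read as one
  affine map $2d \to 2$ with a bias and no hidden layer. A hidden layer is a
  straightforward extension but is not the default.
* **Biases.** The GCN update and the attention map are implemented exactly
  as written above, without bias terms; only the classifier has one.
* **Pair order.** Because $U \ne V$, the model is not symmetric in the order
  of the two proteins; `predict_pair(g1, g2, ...)` and
  `predict_pair(g2, g1, ...)` generally differ. This asymmetry is kept as
  part of the architecture.
* **Subgraph key semantics.** The 1-neighborhood key uses the center label
  and the neighbor label multiset, ignoring edges among the neighbors —
  the canonical "fingerprint" reading, cheap and order-independent.
* **Threshold boundary.** Strictly less than 9.5 Å places an edge; exactly
  9.5 Å does not.
* **Initialization.** All weight matrices use a uniform Glorot-style
  fan-based scheme, seeded; the classifier bias starts at zero. Softmaxes are
  computed with max subtraction; cross-entropy probabilities are floored at
  $10^{-12}$.

## Training protocol

`train_model()` minimizes binary cross-entropy with Adam at learning rate
$10^{-3}$, halved every 10 epochs, for 50 epochs. When the training pool
exceeds 800 pairs, each epoch draws 800 pairs with replacement
(`epoch_sample()`); smaller pools are processed in full, reshuffled each
epoch. Updates are per pair by default (batch size 1), which is the natural
contract when every graph has its own size; results do not depend on any
padding scheme. All randomness flows from one master seed split into named
streams (vocabulary, initialization, folds, epoch sampling), so a
configuration reproduces exactly. The per-pair fused forward/backward pass
is compiled (RcppArmadillo); its analytic gradients are verified against
central finite differences of the plain-R forward pass in the test suite, at
relative tolerance $10^{-4}$ with an absolute floor of $10^{-6}$ on the
denominator (components whose true gradient is $\sim 10^{-8}$ are dominated
by round-off in the finite difference itself).

Resampling utilities mirror the evaluation protocol: stratified $k$-fold
splits whose fold sizes and per-fold class counts differ by at most one
(`split_folds()`), and bootstrap resampling with out-of-bag test sets
(`bootstrap_split()`).

## Evaluation suite

`compute_metrics()` reports accuracy, precision, recall, specificity, NPV,
F1 and Matthews correlation from a 2x2 confusion matrix; ratios with zero
denominators are reported as missing rather than zero, so averages across
folds are not silently inflated. `roc_auc()` is the Mann-Whitney
probability with ties counted one half. `prevalence_corrected_pr()`
recomputes precision at each threshold as $Se / (Se + r(1 - Sp))$,
re-weighting negatives to a deployment ratio of $r$ negatives per positive
($r = 100$ by default); the curve appends a terminal recall-0 point whose
undefined precision carries over from the strictest threshold, so perfect
separation yields area exactly 1. `welch_one_sided()` implements the
unequal-variance $t$-test with Welch-Satterthwaite degrees of freedom for
comparing per-fold metrics between classifiers.

`memorization_test()` probes whether pair labels are predictable from
protein *identity* alone: each pair becomes the sum of its two one-hot
protein vectors (order-invariant) and is handed to a generic classifier
(random forest by default). Chance-level held-out accuracy on this encoding,
alongside high accuracy for the structural model, is evidence that the
latter learns from structure rather than memorizing which proteins appear in
positive pairs.

## The synthetic study: what it emulates, and what it does not

Real curated PPI corpora need thousands of PDB files; the package instead
ships a generator (`make_dataset()`) whose output exercises every stage of
the pipeline with known ground truth.

* **Geometry.** Chains are persistent self-avoiding random walks: steps of
  3.8 ± 0.1 Å (Cα-like spacing), any two centroids at least 3.0 Å apart,
  direction persistence 0.7. This yields connected contact graphs with
  off-backbone spatial contacts, like real globules in coarse outline.
* **Interaction rule.** A contiguous window of 6 residues is relabelled from
  a motif alphabet: lysine for type α carriers, glutamate for type β. A pair
  interacts *iff* one protein carries α and the other β — a
  charge-complementarity caricature. Negatives are drawn from (none, none),
  (α, none), (none, β), (α, α) and (β, β), so no single protein's features
  determine the label, and every protein appears in exactly one pair, so
  identity memorization cannot work at all. The planted window is the
  ground-truth "interface" for scoring attention.
* **Alphabets.** Non-motif residues are drawn from {ALA, GLY, SER}. The
  alphabets are deliberately small: with fixed random embeddings keyed on
  (center, neighbor multiset), generalization to held-out proteins requires
  that their keys recur in the training dictionary, as local neighborhoods
  recur across real structures. With these defaults over 99% of held-out
  vertex keys are covered; with a 10-letter background, coverage collapses
  to ~12% and no architecture could transfer.
* **What it does not emulate.** No side chains, no physical energetics, no
  sequence-structure correlations, no label noise, and a signal
  (6 planted residues out of 40–80) far cleaner than real interfaces.
  Passing the synthetic study therefore validates the machinery — graph
  construction, gradients, optimization, attention bookkeeping — not
  real-world accuracy; the headline accuracies reported for the method on
  curated corpora are out of this package's desk-scale reach.

The study conditions used throughout the tests and the acceptance script:
500 balanced pairs (1000 proteins of 40–80 residues), split 400/100 by one
stratified fold, trained at the default hyperparameters ($d = 20$, $l = 2$,
50 epochs). At these sizes a training run takes well under a minute on one
CPU; the null control repeats training five times under 5-fold
cross-validation with randomized labels and should sit at chance
(accuracy 0.4–0.6).

## Degenerate inputs and numerical corners

* Residues with zero retained heavy atoms are skipped with a warning during
  coarse-graining; duplicate centroids at distance zero still receive an
  edge (with a warning) rather than crashing the normalization.
* $A + I$ guarantees strictly positive degrees, so the normalized adjacency
  is always defined, including isolated vertices.
* Top-20% flagging uses $\lceil 0.2N \rceil$ residues; ties at the cutoff
  break by ascending residue number, making flag sets deterministic and
  independent of storage order.
* When one protein appears in several pairs, importance profiles are
  per-pair; aggregation (e.g. mean $p$ across partners) is left to the
  caller, since no canonical aggregation exists.

## Known limitations

* Single chain per protein; no mmCIF, no biological-assembly expansion.
* Fixed (untrained) vertex embeddings; trainable embeddings, multi-head
  attention, edge features and distance-weighted adjacency are out of scope.
* The attention profile flags residues important for the *prediction*,
  which may include fold-critical rather than interface residues; the two
  cannot be distinguished from this signal alone.
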