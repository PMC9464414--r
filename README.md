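# struct2graph

Structure-based prediction of protein–protein interaction (PPI) with a
mutual graph attention network, for structural bioinformaticians who have 3D
coordinates but no sequence-derived features. Each protein is reduced to its
residue centroids and a contact graph (edge when centroids are closer than
9.5 Å); a weight-shared graph convolutional network (GCN) embeds both
graphs; a mutual attention mechanism couples every residue of one protein to
every residue of the other and compresses each protein into a context
vector; a softmax head turns the pair into an interaction probability. The
per-residue attention probabilities double as an unsupervised ranking of
residues likely to matter for the interaction.

The model, for a pair of graphs with normalized adjacencies
$\tilde A^{(m)} = \hat D^{-1/2}(A^{(m)} + I)\hat D^{-1/2}$ and fixed random
unit-norm vertex embeddings $X_0^{(m)}$:

```
X_{t+1} = ReLU(Ã X_t W_t),  t = 0 … l−1        (shared W_t, h = X_l)
α_ij    = wᵀ tanh(U h_i⁽¹⁾ + V h_j⁽²⁾)          (mutual attention)
η⁽¹⁾    = row means of α;  p⁽¹⁾ = softmax(η⁽¹⁾);  s⁽¹⁾ = Σ p_i⁽¹⁾ h_i⁽¹⁾
y_out   = softmax(F [s⁽¹⁾; s⁽²⁾] + b)            (P(interact) = y_out[2])
```

Training follows the published protocol: Adam at 10⁻³ halved every 10
epochs, 50 epochs, binary cross-entropy, 800 pairs resampled per epoch,
stratified 5-fold cross-validation and bootstrap out-of-bag splits. The
evaluation suite covers accuracy, precision, recall, specificity, MCC, F1,
ROC-AUC, NPV, prevalence-corrected precision–recall curves (r = 100), a
one-sided Welch t-test for comparing classifiers, and a one-hot
"memorization" diagnostic. A seeded generator writes genuine PDB files with
planted complementary interaction motifs so the whole pipeline is testable
without downloading structures.

## Worked example

```r
library(struct2graph)

# a small synthetic study: 100 labelled pairs, 200 proteins as PDB-style clouds
spec   <- synthetic_spec(n_pos = 50, n_neg = 50, seed = 7)
data   <- make_dataset(spec)
graphs <- dataset_graphs(data)
vocab  <- build_vocabulary(graphs, graph_config())

folds <- split_folds(data$pairs$label, k = 5, seed = 1)
fit <- train_model(data$pairs[-folds[[1]], ], graphs, vocab,
                   train_config(seed = 1))
scores <- score_pairs(data$pairs[folds[[1]], ], graphs, vocab, fit$params)
evaluate_scores(scores, data$pairs$label[folds[[1]]])
#>   accuracy precision recall specificity       mcc        f1       npv roc_auc
#> 1     0.85 0.8888889    0.8         0.9 0.7035265 0.8421053 0.8181818     0.9

pred <- predict_pair(graphs[[1]], graphs[[2]], vocab, fit$params)
pred
#> <s2g_prediction> synth0001 + synth0002: P(interact) = 0.9626
head(importance_profile(pred, which = 1), 3)
#>   structure_id seq_id icode  aa            p rank flagged
#> 1    synth0001      1       SER 2.193106e-04   28   FALSE
#> 2    synth0001      2       GLY 9.135630e-05   35   FALSE
#> 3    synth0001      3       GLY 4.468984e-05   39   FALSE
```

Held-out accuracy is 0.85 on this deliberately small study (80 training
pairs; the full 500-pair study used by the test suite reaches ~0.98).
`importance_profile()` ranks residues by their knowledge-selection
probability `p`; the `flagged` column marks the top 20%. On this
interacting pair the flags cover the entire planted 6-residue motif window
(residues 38–43 of `synth0001`) — the model finds the "interface" without
ever being told where it is.

Real structures go through the same surface: `parse_pdb("file.pdb", chain =
"A")`, `coarse_grain()`, `build_graph()`. A thin command-line front end for
simulation, PDB conversion, and score evaluation is in `inst/cli/s2g.R`.

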