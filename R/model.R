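# The mutual graph attention classifier: weight-shared GCN encoder, mutual
# attention, knowledge selection, and the softmax classifier head.
#
# Forward operations are plain R matrix code; the fused per-pair
# forward+backward used by the training loop is compiled (src/).

#' Initialize model parameters
#'
#' All weight matrices use a uniform Glorot-style fan-based scheme,
#' `U(-sqrt(6/(fan_in+fan_out)), +...)`; the classifier bias starts at zero.
#' The GCN weight matrices are shared between the two proteins of a pair.
#'
#' @param l Number of GCN layers (default 2).
#' @param d Embedding dimension (default 20).
#' @param seed Integer seed; the same seed reproduces parameters exactly.
#' @return An object of class `s2g_params`: `W` (list of `l` `d x d`
#'   matrices), attention parameters `U`, `V` (`d x d`) and `w` (length `d`),
#'   classifier weights `Fw` (`2 x 2d`) and bias `Fb` (length 2), plus `l`,
#'   `d`, `seed`.
#' @export
init_params <- function(l = 2L, d = 20L, seed = 0L) {
  if (l < 1) stop("need at least one GCN layer")
  if (d < 1) stop("embedding dimension must be >= 1")
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- with_seed(derive_seed(seed, "init"), {
    list(W = lapply(seq_len(l), function(t) glorot(d, d)),
         U = glorot(d, d),
         V = glorot(d, d),
         w = runif(d, -sqrt(6 / (d + 1)), sqrt(6 / (d + 1))),
         Fw = glorot(2L, 2L * d),
         Fb = c(0, 0))
  })
  structure(c(p, list(l = as.integer(l), d = as.integer(d),
                      seed = as.integer(seed))),
            class = "s2g_params")
}

#' @export
print.s2g_params <- function(x, ...) {
  cat("<s2g_params> l = ", x$l, ", d = ", x$d, " (",
      length(flatten_params(x)), " parameters)\n", sep = "")
  invisible(x)
}

# Flatten/unflatten between the parameter blocks and one numeric vector
# (used by the optimizer and by finite-difference checks).
flatten_params <- function(params) {
  c(unlist(params$W), as.vector(params$U), as.vector(params$V), params$w,
    as.vector(params$Fw), params$Fb)
}

unflatten_params <- function(theta, params) {
  d <- params$d; l <- params$l
  pos <- 0
  take <- function(n) {
    out <- theta[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  params$W <- lapply(seq_len(l), function(t) matrix(take(d * d), d, d))
  params$U <- matrix(take(d * d), d, d)
  params$V <- matrix(take(d * d), d, d)
  params$w <- take(d)
  params$Fw <- matrix(take(2 * d * 2), 2, 2 * d)
  params$Fb <- take(2)
  stopifnot(pos == length(theta))
  params
}

#' GCN forward pass
#'
#' Applies `X_{t+1} = ReLU(Atil %*% X_t %*% W_t)` for `t = 0, ..., l-1` and
#' returns the final embedding `h = X_l`. The same weights are used for both
#' proteins of a pair (weight sharing).
#'
#' @param X0 `N x d` initial vertex features (from [embed_vertices()]).
#' @param Atil `N x N` normalized adjacency (from [normalized_adjacency()]).
#' @param params An `s2g_params`.
#' @return An `N x d` matrix with nonnegative entries.
#' @export
gcn_forward <- function(X0, Atil, params) {
  stopifnot(nrow(X0) == nrow(Atil), ncol(X0) == params$d)
  X <- X0
  for (t in seq_len(params$l)) {
    X <- pmax(Atil %*% X %*% params$W[[t]], 0)
  }
  X
}

#' Mutual attention scores
#'
#' `alpha[i, j] = w' tanh(U h1_i + V h2_j)` for every residue i of protein 1
#' and j of protein 2.
#'
#' @param h1,h2 GCN embeddings (`N1 x d`, `N2 x d`).
#' @param params An `s2g_params`.
#' @return An `N1 x N2` matrix.
#' @export
attention_scores <- function(h1, h2, params) {
  stopifnot(ncol(h1) == params$d, ncol(h2) == params$d)
  P <- h1 %*% t(params$U)  # N1 x d, row i = (U h1_i)'
  Q <- h2 %*% t(params$V)  # N2 x d
  n1 <- nrow(P); n2 <- nrow(Q)
  Tm <- tanh(P[rep(seq_len(n1), times = n2), , drop = FALSE] +
             Q[rep(seq_len(n2), each = n1), , drop = FALSE])
  matrix(Tm %*% params$w, n1, n2)
}

#' Knowledge selection
#'
#' Averages the attention matrix over the partner protein into per-residue
#' scores `eta`, softmaxes them (max-subtracted) into probability vectors
#' `p1`, `p2`, and forms context vectors `s1`, `s2` as the p-weighted means
#' of the GCN embeddings.
#'
#' @param alpha `N1 x N2` attention matrix.
#' @param h1,h2 GCN embeddings.
#' @return A list of class `s2g_attention`: `alpha`, `eta1`, `eta2`, `p1`,
#'   `p2`, `s1`, `s2`.
#' @export
knowledge_select <- function(alpha, h1, h2) {
  stopifnot(nrow(alpha) == nrow(h1), ncol(alpha) == nrow(h2))
  eta1 <- rowMeans(alpha)
  eta2 <- colMeans(alpha)
  p1 <- softmax(eta1)
  p2 <- softmax(eta2)
  structure(
    list(alpha = alpha, eta1 = eta1, eta2 = eta2, p1 = p1, p2 = p2,
         s1 = as.vector(crossprod(h1, p1)), s2 = as.vector(crossprod(h2, p2))),
    class = "s2g_attention"
  )
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classifier head
#'
#' A single affine map from the concatenated context vectors (length `2d`) to
#' two logits, followed by a softmax over the classes (0 = non-interacting,
#' 1 = interacting).
#'
#' @param s1,s2 Context vectors of length `d`.
#' @param params An `s2g_params`.
#' @return A probability 2-vector `c(p_class0, p_class1)` summing to 1.
#' @export
classify <- function(s1, s2, params) {
  stopifnot(length(s1) == params$d, length(s2) == params$d)
  softmax(as.vector(params$Fw %*% c(s1, s2)) + params$Fb)
}

#' Predict the interaction probability for a pair of graphs
#'
#' Composes [embed_vertices()], [normalized_adjacency()], [gcn_forward()]
#' (same weights for both proteins), [attention_scores()],
#' [knowledge_select()] and [classify()]. The output is deterministic given
#' graphs, vocabulary and parameters. Note the architecture is not symmetric
#' in pair order (`U` acts on the first protein, `V` on the second).
#'
#' @param g1,g2 `s2g_graph` objects.
#' @param vocab An `s2g_vocab`.
#' @param params An `s2g_params`.
#' @param symmetrize If `TRUE`, `y_out` is averaged over both pair orders,
#'   removing the architecture's order asymmetry; the attention artifacts
#'   are still reported for the `(g1, g2)` order. Default `FALSE`.
#' @return An object of class `s2g_prediction`: `y_out` (probability
#'   2-vector), `p_interact` (scalar, `y_out[2]`), `attention`
#'   (`s2g_attention`), and the two structure ids.
#' @export
predict_pair <- function(g1, g2, vocab, params, symmetrize = FALSE) {
  f1 <- pair_features(g1, vocab)
  f2 <- pair_features(g2, vocab)
  pred <- predict_pair_features(f1, f2, params,
                                ids = c(g1$structure_id, g2$structure_id),
                                graphs = list(g1, g2))
  if (symmetrize) {
    rev <- predict_pair_features(f2, f1, params)
    pred$y_out <- (pred$y_out + rev$y_out[1:2]) / 2
    pred$p_interact <- pred$y_out[2]
  }
  pred
}

# Precomputed per-protein inputs (reused across epochs during training).
pair_features <- function(g, vocab) {
  list(X0 = embed_vertices(g, vocab), Atil = normalized_adjacency(g))
}

predict_pair_features <- function(f1, f2, params, ids = c(NA, NA),
                                  graphs = NULL) {
  h1 <- gcn_forward(f1$X0, f1$Atil, params)
  h2 <- gcn_forward(f2$X0, f2$Atil, params)
  alpha <- attention_scores(h1, h2, params)
  att <- knowledge_select(alpha, h1, h2)
  y <- classify(att$s1, att$s2, params)
  structure(
    list(y_out = y, p_interact = y[2], attention = att,
         structure_id_1 = ids[1], structure_id_2 = ids[2], graphs = graphs),
    class = "s2g_prediction"
  )
}

#' @export
print.s2g_prediction <- function(x, ...) {
  cat("<s2g_prediction> ", x$structure_id_1, " + ", x$structure_id_2,
      ": P(interact) = ", format(x$p_interact, digits = 4), "\n", sep = "")
  invisible(x)
}
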