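# Residue contact graphs, the 1-neighborhood subgraph vocabulary, and the
# fixed random unit-norm vertex embeddings.

#' Graph construction configuration
#'
#' @param threshold Contact distance threshold in Angstrom between residue
#'   centroids. Two residues are connected when their centroid distance is
#'   strictly below this value (default 9.5).
#' @param d Embedding dimension of the vertex feature vectors (default 20).
#' @param vocab_seed Integer seed controlling the random unit-norm vectors
#'   assigned to subgraph-dictionary entries.
#' @return A list of class `s2g_graph_config`.
#' @export
graph_config <- function(threshold = 9.5, d = 20L, vocab_seed = 1L) {
  stopifnot(threshold > 0, d >= 1)
  structure(list(threshold = threshold, d = as.integer(d),
                 vocab_seed = as.integer(vocab_seed)),
            class = "s2g_graph_config")
}

#' Build a residue contact graph from a cloud
#'
#' Places an edge between residues i and j whenever
#' `0 < ||centroid_i - centroid_j|| < threshold` (strict inequality, no
#' self-edges). Coincident centroids of distinct residues still receive an
#' edge, with a warning; a disconnected graph also warns but is returned.
#'
#' @param cloud An `s2g_cloud`.
#' @param cfg A [graph_config()].
#' @return An object of class `s2g_graph`: `structure_id`, `seq_id`, `icode`,
#'   `labels`, `N`, and the symmetric 0/1 adjacency matrix `A` with zero
#'   diagonal.
#' @export
build_graph <- function(cloud, cfg = graph_config()) {
  validate_cloud(cloud)
  n <- nrow(cloud$centroids)
  dmat <- as.matrix(stats::dist(cloud$centroids))
  A <- matrix(0, n, n)
  A[dmat < cfg$threshold] <- 1
  diag(A) <- 0
  if (n > 1) {
    off <- dmat[upper.tri(dmat)]
    if (any(off == 0)) {
      warning("duplicate centroids at zero distance in ", cloud$structure_id,
              "; edge placed anyway")
      A[dmat == 0] <- 1
      diag(A) <- 0
    }
    if (!is_connected(A)) {
      warning("contact graph of ", cloud$structure_id, " is disconnected")
    }
  }
  structure(
    list(structure_id = cloud$structure_id, seq_id = cloud$seq_id,
         icode = cloud$icode, labels = cloud$labels, N = n, A = A),
    class = "s2g_graph"
  )
}

is_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' @export
print.s2g_graph <- function(x, ...) {
  cat("<s2g_graph> ", x$structure_id, ": ", x$N, " vertices, ",
      sum(x$A) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Symmetrically normalized adjacency matrix
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I`. Adding the identity guarantees strictly positive degrees, so the
#' normalization is always defined.
#'
#' @param g An `s2g_graph`, or a plain 0/1 adjacency matrix.
#' @return A symmetric `N x N` matrix with nonnegative entries.
#' @export
normalized_adjacency <- function(g) {
  A <- if (inherits(g, "s2g_graph")) g$A else as.matrix(g)
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  dinv * Ahat * rep(dinv, each = nrow(A))
}

#' Canonical 1-neighborhood subgraph key of a vertex
#'
#' The key is the vertex's own amino-acid label together with the sorted
#' multiset of its 1-hop neighbors' labels; two vertices with the same label
#' and neighbor multiset produce identical keys regardless of neighbor order.
#'
#' @param g An `s2g_graph`.
#' @param i Vertex index (1-based).
#' @return A single string, e.g. `"ALA|GLY,GLY,SER"`.
#' @export
subgraph_key <- function(g, i) {
  stopifnot(i >= 1, i <= g$N)
  nb <- which(g$A[i, ] > 0)
  paste0(g$labels[i], "|", paste(sort(g$labels[nb]), collapse = ","))
}

subgraph_keys <- function(g) {
  vapply(seq_len(g$N), function(i) subgraph_key(g, i), character(1))
}

# Deterministic unit-norm vector for a key: isotropic Gaussian draw seeded by
# (vocab_seed, key hash), then normalized. Because each key's vector depends
# only on the seed and the key itself, vocabulary content is independent of
# the order in which graphs are scanned, and unseen keys on held-out proteins
# embed reproducibly through the same mechanism.
key_vector <- function(key, d, vocab_seed) {
  v <- with_seed(mix_seed(vocab_seed, stable_hash(key)), rnorm(d))
  v / sqrt(sum(v^2))
}

#' Build the subgraph vocabulary over a collection of graphs
#'
#' Scans all graphs, records each unique 1-neighborhood key in first-seen
#' order, and assigns every key an independent random unit-norm vector in
#' `R^d`, reproducible from `cfg$vocab_seed`.
#'
#' @param graphs A list of `s2g_graph` objects.
#' @param cfg A [graph_config()].
#' @return An object of class `s2g_vocab`: `keys` (character vector), `E`
#'   (`|vocab| x d` matrix of unit-norm rows), `d`, `vocab_seed`.
#' @export
build_vocabulary <- function(graphs, cfg = graph_config()) {
  if (length(graphs) == 0) stop("cannot build a vocabulary from zero graphs")
  keys <- unique(unlist(lapply(graphs, subgraph_keys)))
  E <- t(vapply(keys, key_vector, numeric(cfg$d),
                d = cfg$d, vocab_seed = cfg$vocab_seed))
  dimnames(E) <- NULL
  structure(list(keys = keys, E = E, d = cfg$d, vocab_seed = cfg$vocab_seed),
            class = "s2g_vocab")
}

#' @export
print.s2g_vocab <- function(x, ...) {
  cat("<s2g_vocab> ", length(x$keys), " subgraph keys, d = ", x$d, "\n",
      sep = "")
  invisible(x)
}

#' Embed the vertices of a graph using a vocabulary
#'
#' Row i of the result is the vocabulary vector of vertex i's subgraph key.
#' Keys absent from the vocabulary (novel neighborhoods on held-out proteins)
#' fall back to the same deterministic hash-seeded unit-norm construction, so
#' embedding is always defined and reproducible.
#'
#' @param g An `s2g_graph`.
#' @param vocab An `s2g_vocab`.
#' @return An `N x d` matrix of unit-norm rows.
#' @export
embed_vertices <- function(g, vocab) {
  keys <- subgraph_keys(g)
  idx <- match(keys, vocab$keys)
  X0 <- matrix(0, g$N, vocab$d)
  hit <- !is.na(idx)
  if (any(hit)) X0[hit, ] <- vocab$E[idx[hit], , drop = FALSE]
  for (i in which(!hit)) {
    X0[i, ] <- key_vector(keys[i], vocab$d, vocab$vocab_seed)
  }
  X0
}
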