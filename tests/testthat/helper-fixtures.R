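# Shared fixtures, built in code. Heavy objects are memoized so several test
# files (and several acceptance blocks) can reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small labelled dataset with graphs and vocabulary (20 pairs).
small_world <- function() {
  memo("small_world", {
    spec <- synthetic_spec(n_pos = 10, n_neg = 10, chain_length = c(20L, 30L),
                           seed = 101)
    data <- make_dataset(spec)
    graphs <- suppressWarnings(dataset_graphs(data))
    vocab <- build_vocabulary(graphs, graph_config())
    list(spec = spec, data = data, graphs = graphs, vocab = vocab)
  })
}

# A random cloud with the given number of residues (seeded).
random_cloud <- function(n, seed, labels = NULL) {
  with_seed_test(seed, {
    struct2graph:::new_cloud(
      structure_id = paste0("rnd", seed),
      seq_id = seq_len(n),
      labels = labels %||% sample(c("ALA", "GLY", "SER", "LYS", "GLU"), n,
                                  replace = TRUE),
      centroids = matrix(stats::rnorm(n * 3, sd = 8), n, 3)
    )
  })
}

# Seed scoping for tests, without touching the session RNG.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A graph built directly from an adjacency matrix and labels (no geometry).
graph_from_adjacency <- function(A, labels, id = "adhoc") {
  structure(
    list(structure_id = id, seq_id = seq_len(nrow(A)),
         icode = rep("", nrow(A)), labels = labels, N = nrow(A),
         A = A),
    class = "s2g_graph"
  )
}

# Full R-side forward pass to a BCE loss, for finite-difference checks.
forward_loss <- function(theta, template, f1, f2, label) {
  p <- struct2graph:::unflatten_params(theta, template)
  h1 <- gcn_forward(f1$X0, f1$Atil, p)
  h2 <- gcn_forward(f2$X0, f2$Atil, p)
  att <- knowledge_select(attention_scores(h1, h2, p), h1, h2)
  bce_loss(classify(att$s1, att$s2, p), label)
}
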