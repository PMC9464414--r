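# Encoder, mutual attention, knowledge selection, classifier head, and the
# analytic gradients of the fused training pass.

test_that("parameter initialization is seeded, shaped, and validated", {
  p1 <- init_params(l = 2, d = 20, seed = 0)
  p2 <- init_params(l = 2, d = 20, seed = 0)
  expect_identical(p1, p2)
  expect_equal(length(p1$W), 2)
  expect_equal(dim(p1$W[[1]]), c(20, 20))
  expect_equal(dim(p1$U), c(20, 20))
  expect_equal(dim(p1$V), c(20, 20))
  expect_equal(length(p1$w), 20)
  expect_equal(dim(p1$Fw), c(2, 40))
  expect_equal(length(p1$Fb), 2)
  expect_error(init_params(l = 0), "at least one")
  expect_false(identical(p1$U, init_params(seed = 1)$U))
})

test_that("flatten/unflatten round-trips every parameter block", {
  p <- init_params(l = 3, d = 5, seed = 2)
  th <- struct2graph:::flatten_params(p)
  expect_identical(struct2graph:::unflatten_params(th, p), p)
})

test_that("gcn_forward matches closed forms and a per-vertex message-passing oracle", {
  # single vertex, identity weights, one layer: ReLU of x0
  p <- init_params(l = 1, d = 2, seed = 0)
  p$W[[1]] <- diag(2)
  h <- gcn_forward(matrix(c(0.5, -0.2), 1, 2), matrix(1, 1, 1), p)
  expect_equal(as.vector(h), c(0.5, 0))

  # complete graph with identical nonnegative rows is a fixed point under W = I
  v <- c(0.3, 0.7)
  X0 <- matrix(v, 4, 2, byrow = TRUE)
  A <- matrix(1, 4, 4) - diag(4)
  At <- normalized_adjacency(graph_from_adjacency(A, rep("ALA", 4)))
  p2 <- init_params(l = 2, d = 2, seed = 0)
  p2$W <- list(diag(2), diag(2))
  expect_equal(gcn_forward(X0, At, p2), X0, tolerance = 1e-12)

  # random graph vs naive double-loop implementation of the update rule
  with_seed_test(5, {
    n <- 6; d <- 4
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.5)
    A <- A + t(A)
    At <- normalized_adjacency(graph_from_adjacency(A, rep("ALA", n)))
    X0 <- matrix(stats::rnorm(n * d), n, d)
    p3 <- init_params(l = 2, d = d, seed = 9)
    naive <- X0
    for (t in 1:2) {
      nxt <- matrix(0, n, d)
      for (i in 1:n) {
        agg <- numeric(d)
        for (j in 1:n) agg <- agg + At[i, j] * naive[j, ]
        nxt[i, ] <- pmax(as.vector(agg %*% p3$W[[t]]), 0)
      }
      naive <- nxt
    }
    expect_equal(gcn_forward(X0, At, p3), naive, tolerance = 1e-9)
  })
  expect_error(gcn_forward(matrix(0, 2, 3), matrix(1, 1, 1), init_params(d = 3)))
})

test_that("attention scores match the scalar formula and a double-loop oracle", {
  # U = V = 0 gives identically zero attention
  p <- init_params(l = 1, d = 3, seed = 0)
  p$U <- matrix(0, 3, 3); p$V <- matrix(0, 3, 3)
  h1 <- matrix(stats::rnorm(12), 4, 3)
  h2 <- matrix(stats::rnorm(6), 2, 3)
  expect_equal(attention_scores(h1, h2, p), matrix(0, 4, 2), tolerance = 1e-15)

  # d = 1 worked value: alpha = 2 * tanh(1)
  p1 <- init_params(l = 1, d = 1, seed = 0)
  p1$U <- matrix(1, 1, 1); p1$V <- matrix(1, 1, 1); p1$w <- 2
  a <- attention_scores(matrix(1, 1, 1), matrix(0, 1, 1), p1)
  expect_equal(a[1, 1], 2 * tanh(1), tolerance = 1e-12)
  expect_equal(a[1, 1], 1.5232, tolerance = 1e-4)

  # random case vs elementwise double loop
  with_seed_test(11, {
    d <- 5
    p5 <- init_params(l = 1, d = d, seed = 3)
    h1 <- matrix(stats::rnorm(4 * d), 4, d)
    h2 <- matrix(stats::rnorm(3 * d), 3, d)
    alpha <- attention_scores(h1, h2, p5)
    for (i in 1:4) for (j in 1:3) {
      expect_equal(alpha[i, j],
                   sum(p5$w * tanh(p5$U %*% h1[i, ] + p5$V %*% h2[j, ])),
                   tolerance = 1e-9)
    }
    expect_true(all(abs(alpha) <= sum(abs(p5$w))))
  })
})

test_that("knowledge selection computes softmax probabilities and convex context vectors", {
  h1 <- matrix(stats::rnorm(8), 4, 2)
  h2 <- matrix(stats::rnorm(6), 3, 2)
  # constant attention: uniform p, mean-row context
  att <- knowledge_select(matrix(3.7, 4, 3), h1, h2)
  expect_equal(att$p1, rep(1 / 4, 4), tolerance = 1e-12)
  expect_equal(att$p2, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(att$s1, colMeans(h1), tolerance = 1e-12)
  expect_equal(att$s2, colMeans(h2), tolerance = 1e-12)

  # closed-form softmax: eta = (0, ln 3) -> p = (0.25, 0.75)
  # build alpha whose row means are (0, ln 3)
  alpha <- cbind(c(0, log(3)), c(0, log(3)))
  h1b <- matrix(c(1, 0, 0, 1), 2, 2)
  h2b <- matrix(stats::rnorm(4), 2, 2)
  attb <- knowledge_select(alpha, h1b, h2b)
  expect_equal(attb$p1, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(attb$s1, 0.25 * h1b[1, ] + 0.75 * h1b[2, ], tolerance = 1e-12)

  # probability vectors always sum to one; s lies in the rows' convex hull
  with_seed_test(2, {
    for (rep in 1:10) {
      a <- matrix(stats::rnorm(12, sd = 5), 4, 3)
      at <- knowledge_select(a, h1, h2)
      expect_equal(sum(at$p1), 1, tolerance = 1e-9)
      expect_equal(sum(at$p2), 1, tolerance = 1e-9)
      expect_true(all(at$p1 > 0) && all(at$p2 > 0))
      expect_true(all(at$s1 >= apply(h1, 2, min) - 1e-12) &&
                    all(at$s1 <= apply(h1, 2, max) + 1e-12))
    }
  })
})

test_that("the classifier head is a softmaxed affine map", {
  p <- init_params(l = 1, d = 3, seed = 0)
  p$Fw <- matrix(0, 2, 6); p$Fb <- c(0, 0)
  expect_equal(classify(rnorm(3), rnorm(3), p), c(0.5, 0.5), tolerance = 1e-12)

  # logits (ln 3, 0) -> (0.75, 0.25)
  p$Fw <- matrix(0, 2, 6); p$Fb <- c(log(3), 0)
  expect_equal(classify(rnorm(3), rnorm(3), p), c(0.75, 0.25), tolerance = 1e-12)

  with_seed_test(3, {
    p2 <- init_params(l = 1, d = 3, seed = 5)
    y <- classify(rnorm(3), rnorm(3), p2)
    expect_equal(sum(y), 1, tolerance = 1e-9)
    expect_true(all(y >= 0 & y <= 1))
  })
})

test_that("predict_pair is deterministic, shape-correct, and order-asymmetric", {
  w <- small_world()
  params <- init_params(seed = 4)
  g1 <- w$graphs[[1]]; g2 <- w$graphs[[2]]
  pr1 <- predict_pair(g1, g2, w$vocab, params)
  pr2 <- predict_pair(g1, g2, w$vocab, params)
  expect_identical(pr1$y_out, pr2$y_out)
  expect_equal(sum(pr1$y_out), 1, tolerance = 1e-9)
  expect_equal(dim(pr1$attention$alpha), c(g1$N, g2$N))

  # symmetrized prediction averages both pair orders
  sym12 <- predict_pair(g1, g2, w$vocab, params, symmetrize = TRUE)
  sym21 <- predict_pair(g2, g1, w$vocab, params, symmetrize = TRUE)
  expect_equal(sym12$y_out, sym21$y_out, tolerance = 1e-12)
  rev <- predict_pair(g2, g1, w$vocab, params)
  expect_equal(sym12$y_out, (pr1$y_out + rev$y_out) / 2, tolerance = 1e-12)

  # d = 1 construction with U = 1, V = 0: swapping the proteins changes alpha
  p1 <- init_params(l = 1, d = 1, seed = 0)
  p1$W[[1]] <- matrix(1, 1, 1)
  p1$U <- matrix(1, 1, 1); p1$V <- matrix(0, 1, 1); p1$w <- 1
  h_a <- matrix(1, 1, 1); h_b <- matrix(0.2, 1, 1)
  a_ab <- attention_scores(h_a, h_b, p1)
  a_ba <- attention_scores(h_b, h_a, p1)
  expect_equal(a_ab[1, 1], tanh(1))
  expect_equal(a_ba[1, 1], tanh(0.2))
  expect_false(isTRUE(all.equal(a_ab, a_ba)))
})

test_that("the encoder is permutation-equivariant and the pair output permutation-invariant", {
  w <- small_world()
  params <- init_params(seed = 6)
  with_seed_test(13, {
    for (rep in 1:10) {
      g <- w$graphs[[sample(length(w$graphs), 1)]]
      X0 <- embed_vertices(g, w$vocab)
      At <- normalized_adjacency(g)
      perm <- sample(g$N)
      h <- gcn_forward(X0, At, params)
      h_p <- gcn_forward(X0[perm, , drop = FALSE],
                         At[perm, perm, drop = FALSE], params)
      expect_equal(h_p, h[perm, , drop = FALSE], tolerance = 1e-9)
    }
    # relabeling vertices of either protein leaves y_out unchanged
    g1 <- w$graphs[[1]]; g2 <- w$graphs[[2]]
    base <- predict_pair(g1, g2, w$vocab, params)
    perm <- sample(g1$N)
    g1p <- g1
    g1p$A <- g1$A[perm, perm]
    g1p$labels <- g1$labels[perm]
    g1p$seq_id <- g1$seq_id[perm]
    g1p$icode <- g1$icode[perm]
    shuf <- predict_pair(g1p, g2, w$vocab, params)
    expect_equal(shuf$y_out, base$y_out, tolerance = 1e-9)
  })
})

test_that("compiled pair loss equals the R forward pass", {
  w <- small_world()
  params <- init_params(seed = 8)
  f1 <- struct2graph:::pair_features(w$graphs[[1]], w$vocab)
  f2 <- struct2graph:::pair_features(w$graphs[[2]], w$vocab)
  for (label in 0:1) {
    res <- struct2graph:::pair_grad_cpp(f1$Atil, f1$X0, f2$Atil, f2$X0,
                                        params$W, params$U, params$V,
                                        params$w, params$Fw, params$Fb, label)
    pr <- predict_pair(w$graphs[[1]], w$graphs[[2]], w$vocab, params)
    expect_equal(res$loss, bce_loss(pr$y_out, label), tolerance = 1e-12)
    expect_equal(as.vector(res$y), pr$y_out, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- graph_config(d = 3)
  spec <- synthetic_spec(n_pos = 1, n_neg = 1, chain_length = c(6L, 9L),
                         seed = 11)
  dset <- make_dataset(spec)
  graphs <- suppressWarnings(dataset_graphs(dset, cfg))
  vocab <- build_vocabulary(graphs, cfg)
  params <- init_params(l = 2, d = 3, seed = 4)
  f1 <- struct2graph:::pair_features(graphs[[1]], vocab)
  f2 <- struct2graph:::pair_features(graphs[[2]], vocab)
  th <- struct2graph:::flatten_params(params)
  for (label in 0:1) {
    res <- struct2graph:::pair_grad_cpp(f1$Atil, f1$X0, f2$Atil, f2$X0,
                                        params$W, params$U, params$V,
                                        params$w, params$Fw, params$Fb, label)
    h <- 1e-5
    fd <- vapply(seq_along(th), function(k) {
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      (forward_loss(tp, params, f1, f2, label) -
         forward_loss(tm, params, f1, f2, label)) / (2 * h)
    }, numeric(1))
    rel <- abs(fd - res$grad) / pmax(abs(fd) + abs(res$grad), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})
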