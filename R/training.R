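# Dataset resampling schemes, the binary cross-entropy loss, and the Adam
# training loop with step-decayed learning rate and per-epoch subsampling.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam at learning rate `1e-3`
#' halved every 10 epochs, 50 epochs, and 800 pairs sampled with replacement
#' per epoch when the training pool is larger than that.
#'
#' @param lr Initial Adam learning rate.
#' @param decay Multiplicative learning-rate decay factor, in (0, 1].
#' @param decay_every Epoch period of the decay.
#' @param epochs Number of training epochs.
#' @param epoch_sample_size Number of pairs drawn (with replacement) per
#'   epoch; if the training pool is smaller, the whole pool is used.
#' @param batch_size Pairs per parameter update (default 1: per-pair updates,
#'   natural for variable-size graphs).
#' @param seed Master seed; named sub-streams (init, epoch sampling) are
#'   derived from it.
#' @return A list of class `s2g_train_config`.
#' @export
train_config <- function(lr = 1e-3, decay = 0.5, decay_every = 10L,
                         epochs = 50L, epoch_sample_size = 800L,
                         batch_size = 1L, seed = 1L) {
  stopifnot(lr > 0, decay > 0, decay <= 1, decay_every >= 1, epochs >= 1,
            epoch_sample_size >= 1, batch_size >= 1)
  structure(list(lr = lr, decay = decay, decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 epoch_sample_size = as.integer(epoch_sample_size),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "s2g_train_config")
}

#' Stratified k-fold split
#'
#' Partitions examples into `k` folds whose sizes differ by at most one and
#' whose per-fold class ratio is within one example of the global ratio.
#'
#' @param labels Binary (0/1) label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors (disjoint, covering all
#'   examples).
#' @export
split_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  if (k < 2) stop("need at least 2 folds")
  if (min(table(factor(labels, levels = 0:1))) < k) {
    stop("need at least k examples of each class")
  }
  folds <- vector("list", k)
  cursor <- 0L
  with_seed(derive_seed(seed, "folds"), {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(labels == cls))
      for (i in seq_along(idx)) {
        f <- (cursor %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[i])
        cursor <- cursor + 1L
      }
    }
  })
  lapply(folds, sort)
}

#' Bootstrap resample with out-of-bag test set
#'
#' Draws `n` examples with replacement as the training multiset; the examples
#' never drawn form the out-of-bag test set (about 36.8% of the data for
#' large `n`).
#'
#' @param n Number of examples.
#' @param seed Integer seed.
#' @return A list with `train` (length-`n` integer multiset) and `oob`
#'   (sorted integer vector of never-drawn indices).
#' @export
bootstrap_split <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  train <- with_seed(derive_seed(seed, "bootstrap"),
                     sample.int(n, n, replace = TRUE))
  list(train = train, oob = sort(setdiff(seq_len(n), unique(train))))
}

#' Per-epoch subsample of the training pool
#'
#' Draws `m` indices from `pool` with replacement, seeded by `(seed, epoch)`
#' so each epoch sees a fresh but reproducible sample.
#'
#' @param pool Integer vector of candidate indices.
#' @param m Number of draws.
#' @param seed Master seed.
#' @param epoch Epoch number (part of the stream seed).
#' @return An integer vector of length `m` (duplicates allowed).
#' @export
epoch_sample <- function(pool, m = 800L, seed = 1L, epoch = 1L) {
  stopifnot(length(pool) >= 1)
  with_seed(derive_seed(seed, "epoch", epoch),
            pool[sample.int(length(pool), m, replace = TRUE)])
}

#' Binary cross-entropy of a probability pair
#'
#' @param y_out Probability 2-vector `c(p_class0, p_class1)`.
#' @param label 0 or 1.
#' @return `-log(y_out[label + 1])`, with probabilities floored at `1e-12`.
#' @export
bce_loss <- function(y_out, label) {
  stopifnot(length(y_out) == 2, label %in% c(0, 1))
  -log(max(y_out[label + 1], 1e-12))
}

# Precompute X0/Atil for every structure referenced by a pair table.
precompute_features <- function(pairs, graphs, vocab) {
  ids <- unique(c(pairs$id1, pairs$id2))
  missing <- setdiff(ids, names(graphs))
  if (length(missing)) stop("graphs missing for: ", paste(missing, collapse = ", "))
  feats <- lapply(graphs[ids], pair_features, vocab = vocab)
  names(feats) <- ids
  feats
}

#' Train the mutual graph attention classifier
#'
#' Adam optimization of the binary cross-entropy over labelled protein pairs,
#' with the learning rate multiplied by `cfg$decay` every `cfg$decay_every`
#' epochs. Each epoch processes an [epoch_sample()] of the pool when the pool
#' exceeds `cfg$epoch_sample_size`, otherwise the whole pool in a random
#' order. Fully reproducible from `cfg$seed`.
#'
#' @param pairs Data frame with columns `id1`, `id2` (names into `graphs`)
#'   and `label` (0/1).
#' @param graphs Named list of `s2g_graph` objects.
#' @param vocab An `s2g_vocab`.
#' @param cfg A [train_config()].
#' @param val_pairs Optional data frame like `pairs`; if given, per-epoch
#'   validation accuracy (threshold 0.5 on the class-1 probability) is
#'   recorded in the history.
#' @param init Optional `s2g_params` to start from; defaults to
#'   [init_params()] seeded from `cfg$seed`.
#' @param l,d Architecture hyperparameters forwarded to [init_params()] when
#'   `init` is not supplied.
#' @param verbose Print per-epoch mean loss.
#' @return A list of class `s2g_fit`: `params` (trained `s2g_params`),
#'   `history` (`s2g_history` with per-epoch `loss`, `val_accuracy`, `lr`),
#'   `cfg`, and `vocab`.
#' @export
train_model <- function(pairs, graphs, vocab, cfg = train_config(),
                        val_pairs = NULL, init = NULL, l = 2L, d = NULL,
                        verbose = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("id1", "id2", "label") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("empty training set")
  labels <- as.integer(pairs$label)
  if (length(unique(labels)) < 2) stop("training set must contain both classes")
  if (any(pairs$id1 == pairs$id2)) stop("self-pairs are not allowed (heterologous pairs only)")

  d <- d %||% vocab$d
  params <- init %||% init_params(l = l, d = d, seed = cfg$seed)
  stopifnot(params$d == vocab$d)
  feats <- precompute_features(
    if (is.null(val_pairs)) pairs else rbind(pairs[c("id1", "id2", "label")],
                                             val_pairs[c("id1", "id2", "label")]),
    graphs, vocab)

  theta <- flatten_params(params)
  mstate <- numeric(length(theta))
  vstate <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(cfg$epochs)
  val_hist <- rep(NA_real_, cfg$epochs)
  lr_hist <- numeric(cfg$epochs)
  pool <- seq_len(nrow(pairs))
  struct_ids <- names(feats)
  X0s <- lapply(feats, `[[`, "X0")
  Atils <- lapply(feats, `[[`, "Atil")
  pair_i1 <- match(pairs$id1, struct_ids)
  pair_i2 <- match(pairs$id2, struct_ids)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$decay^((epoch - 1) %/% cfg$decay_every)
    lr_hist[epoch] <- lr
    idx <- if (length(pool) > cfg$epoch_sample_size) {
      epoch_sample(pool, cfg$epoch_sample_size, cfg$seed, epoch)
    } else {
      with_seed(derive_seed(cfg$seed, "epoch", epoch), sample(pool))
    }
    if (cfg$batch_size == 1L) {
      res <- epoch_train_cpp(X0s, Atils, pair_i1[idx], pair_i2[idx],
                             labels[idx], theta, mstate, vstate, step, lr,
                             params$l, params$d, b1, b2, eps)
      theta <- as.vector(res$theta)
      mstate <- as.vector(res$m)
      vstate <- as.vector(res$v)
      step <- res$step
      loss_hist[epoch] <- res$mean_loss
      p <- unflatten_params(theta, params)
    } else {
      p <- unflatten_params(theta, params)
      epoch_loss <- 0
      batch_grad <- NULL
      in_batch <- 0L
      for (q in seq_along(idx)) {
        i <- idx[q]
        f1 <- feats[[pairs$id1[i]]]
        f2 <- feats[[pairs$id2[i]]]
        res <- pair_grad_cpp(f1$Atil, f1$X0, f2$Atil, f2$X0, p$W, p$U, p$V,
                             p$w, p$Fw, p$Fb, labels[i])
        epoch_loss <- epoch_loss + res$loss
        batch_grad <- if (is.null(batch_grad)) res$grad else batch_grad + res$grad
        in_batch <- in_batch + 1L
        if (in_batch == cfg$batch_size || q == length(idx)) {
          g <- batch_grad / in_batch
          step <- step + 1L
          mstate <- b1 * mstate + (1 - b1) * g
          vstate <- b2 * vstate + (1 - b2) * g^2
          mhat <- mstate / (1 - b1^step)
          vhat <- vstate / (1 - b2^step)
          theta <- theta - lr * mhat / (sqrt(vhat) + eps)
          p <- unflatten_params(theta, params)
          batch_grad <- NULL
          in_batch <- 0L
        }
      }
      loss_hist[epoch] <- epoch_loss / length(idx)
    }
    if (!is.null(val_pairs)) {
      sc <- score_pairs_features(val_pairs, feats, p)
      val_hist[epoch] <- mean((sc >= 0.5) == (val_pairs$label == 1))
    }
    if (verbose) {
      cat(sprintf("epoch %3d  lr %.2e  loss %.4f%s\n", epoch, lr,
                  loss_hist[epoch],
                  if (is.na(val_hist[epoch])) "" else
                    sprintf("  val acc %.3f", val_hist[epoch])))
    }
  }

  structure(
    list(params = unflatten_params(theta, params),
         history = structure(list(loss = loss_hist, val_accuracy = val_hist,
                                  lr = lr_hist), class = "s2g_history"),
         cfg = cfg, vocab = vocab),
    class = "s2g_fit"
  )
}

#' @export
print.s2g_fit <- function(x, ...) {
  n <- length(x$history$loss)
  cat("<s2g_fit> ", n, " epochs; final mean loss ",
      format(x$history$loss[n], digits = 4), "\n", sep = "")
  invisible(x)
}

score_pairs_features <- function(pairs, feats, params) {
  vapply(seq_len(nrow(pairs)), function(i) {
    predict_pair_features(feats[[pairs$id1[i]]], feats[[pairs$id2[i]]],
                          params)$p_interact
  }, numeric(1))
}

#' Score a table of pairs with a trained model
#'
#' @param pairs Data frame with columns `id1`, `id2` (and optionally `label`).
#' @param graphs Named list of `s2g_graph` objects.
#' @param vocab An `s2g_vocab`.
#' @param params An `s2g_params` (e.g. `fit$params`).
#' @return Numeric vector of interaction probabilities, one per row.
#' @export
score_pairs <- function(pairs, graphs, vocab, params) {
  feats <- precompute_features(pairs, graphs, vocab)
  score_pairs_features(pairs, feats, params)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Trains one model per fold on the remaining folds and scores the held-out
#' fold. Returns per-fold accuracy at threshold 0.5 together with all
#' held-out scores.
#'
#' @inheritParams train_model
#' @param k Number of folds.
#' @return A list with `fold_accuracy` (length `k`), `scores`, `labels`, and
#'   `folds` (the index partition).
#' @export
cross_validate <- function(pairs, graphs, vocab, cfg = train_config(),
                           k = 5L, l = 2L, verbose = FALSE) {
  folds <- split_folds(pairs$label, k = k, seed = cfg$seed)
  scores <- numeric(nrow(pairs))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    fit <- train_model(pairs[-test_idx, , drop = FALSE], graphs, vocab,
                       cfg = cfg, l = l, verbose = verbose)
    sc <- score_pairs(pairs[test_idx, , drop = FALSE], graphs, vocab,
                      fit$params)
    scores[test_idx] <- sc
    acc[f] <- mean((sc >= 0.5) == (pairs$label[test_idx] == 1))
  }
  list(fold_accuracy = acc, scores = scores,
       labels = as.integer(pairs$label), folds = folds)
}
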