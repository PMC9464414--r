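# Internal helpers: seeded RNG scoping and a stable string hash.
#
# All randomness in the package flows through with_seed() so that results are
# reproducible from explicit integer seeds and never disturb the caller's
# global RNG state.

# Evaluate `code` under a temporary RNG seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Stable polynomial hash of a character string into [0, 2^31 - 2].
# Independent of R's serialization, so hash-seeded embeddings are
# reproducible across sessions and platforms.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% m
  h
}

# Mix a key hash with a user seed into a valid set.seed() integer.
mix_seed <- function(seed, h) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

# Derive named sub-seeds from one master seed so independent random streams
# (vocabulary, init, folds, epoch sampling, ...) never collide.
derive_seed <- function(seed, stream, index = 0L) {
  mix_seed(seed, (stable_hash(stream) + 1000003 * as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
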