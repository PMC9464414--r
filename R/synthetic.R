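# Seeded generator of synthetic protein structures and labelled pairs.
#
# Chains are persistent self-avoiding random walks at Calpha-like spacing, so
# the 9.5 Angstrom contact graph is connected along the backbone and has
# nontrivial off-backbone contacts. Interaction is a planted *pairwise*
# property: a pair interacts iff one protein carries a motif from alphabet
# alpha and the other a motif from the disjoint alphabet beta, so no single
# protein's features (and no protein identity) determine the label.

#' Specification of a synthetic dataset
#'
#' @param n_pos,n_neg Numbers of positive and negative pairs.
#' @param chain_length Integer range `c(min, max)` of residues per chain.
#' @param bond_length Consecutive-centroid distance in Angstrom (default 3.8,
#'   mimicking Calpha spacing).
#' @param min_separation Minimum distance between any two centroids (default
#'   3.0 Angstrom, preventing degenerate contacts).
#' @param motif_length Length of the planted motif window (default 6).
#' @param motif_alpha,motif_beta Disjoint amino-acid label sets used to
#'   relabel the two motif types. The defaults (lysine vs glutamate) mimic
#'   charge-complementary interaction motifs.
#' @param background Amino-acid labels of non-motif residues (disjoint from
#'   both motif alphabets). Kept to a small alphabet so that 1-neighborhood
#'   subgraph keys recur across proteins, as they do in real structures -
#'   held-out proteins are then covered by the training dictionary.
#' @param persistence Direction-persistence of the random walk in \[0, 1);
#'   higher values give straighter, more extended chains.
#' @param seed Master seed.
#' @return A list of class `s2g_synth_spec`.
#' @export
synthetic_spec <- function(n_pos = 50L, n_neg = 50L,
                           chain_length = c(40L, 80L),
                           bond_length = 3.8, min_separation = 3.0,
                           motif_length = 6L,
                           motif_alpha = "LYS",
                           motif_beta = "GLU",
                           background = c("ALA", "GLY", "SER"),
                           persistence = 0.7, seed = 1L) {
  stopifnot(length(intersect(motif_alpha, motif_beta)) == 0,
            length(intersect(motif_alpha, background)) == 0,
            length(intersect(motif_beta, background)) == 0,
            chain_length[1] < chain_length[2],
            chain_length[1] >= motif_length,
            bond_length > 0, min_separation > 0, min_separation < 2 * bond_length,
            persistence >= 0, persistence < 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 chain_length = as.integer(chain_length),
                 bond_length = bond_length, min_separation = min_separation,
                 motif_length = as.integer(motif_length),
                 motif_alpha = motif_alpha, motif_beta = motif_beta,
                 background = background, persistence = persistence,
                 seed = as.integer(seed)),
            class = "s2g_synth_spec")
}

# One step candidate: unit direction mixing the previous direction with an
# isotropic random one.
random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate one synthetic chain
#'
#' A persistent self-avoiding random walk of `n` residue centroids:
#' consecutive centroids at `bond_length` (plus or minus at most 0.1
#' Angstrom), every pairwise distance at least `min_separation`, residue
#' labels drawn from the background alphabet. If self-avoidance cannot be
#' satisfied after bounded retries the chain is regenerated from a perturbed
#' seed (with a message), never returned with overlaps.
#'
#' @param n Number of residues (at least 2).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same `(n, seed)` gives identical coordinates.
#' @param structure_id Identifier for the generated structure.
#' @return An `s2g_cloud`.
#' @export
make_chain <- function(n, spec = synthetic_spec(), seed = 1L,
                       structure_id = sprintf("synth%06d", seed)) {
  stopifnot(n >= 2)
  for (attempt in 0:24) {
    cl <- with_seed(derive_seed(seed, "chain", attempt), {
      try_walk(n, spec, structure_id)
    })
    if (!is.null(cl)) {
      if (attempt > 0) {
        message("make_chain: self-avoidance retry succeeded (attempt ",
                attempt + 1, ") for ", structure_id)
      }
      return(cl)
    }
  }
  stop("self-avoiding walk failed repeatedly for n = ", n)
}

try_walk <- function(n, spec, structure_id) {
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- c(0, 0, 0)
  dir <- random_unit()
  for (i in 2:n) {
    placed <- FALSE
    for (k in 1:60) {
      cand_dir <- spec$persistence * dir + (1 - spec$persistence) * random_unit()
      nc <- sqrt(sum(cand_dir^2))
      if (nc < 1e-8) next
      cand_dir <- cand_dir / nc
      step <- spec$bond_length + runif(1, -0.1, 0.1)
      cand <- coords[i - 1, ] + step * cand_dir
      d2 <- colSums((t(coords[seq_len(i - 1), , drop = FALSE]) - cand)^2)
      # the previous residue is bonded; all others must clear min_separation
      ok_prev <- d2[i - 1] >= 0  # bonded distance is the step itself
      ok_rest <- i == 2 || all(d2[seq_len(i - 2)] >= spec$min_separation^2)
      if (ok_prev && ok_rest && step >= spec$min_separation) {
        coords[i, ] <- cand
        dir <- cand_dir
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  labels <- sample(spec$background, n, replace = TRUE)
  new_cloud(structure_id, seq_id = seq_len(n), labels = labels,
            centroids = coords)
}

#' Plant an interaction motif into a chain
#'
#' Relabels a contiguous window of `motif_length` residues with labels drawn
#' from the chosen motif alphabet; coordinates are untouched. The relabelled
#' residues are the ground-truth "interface" of the chain. Because the motif
#' alphabets are disjoint from the background, motif carriers produce
#' subgraph keys that occur nowhere else.
#'
#' @param cloud An `s2g_cloud`.
#' @param type `"alpha"` or `"beta"`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (controls window position and labels).
#' @return A list with `cloud` (relabelled) and `interface` (integer
#'   `seq_id`s of the planted window).
#' @export
plant_motif <- function(cloud, type = c("alpha", "beta"),
                        spec = synthetic_spec(), seed = 1L) {
  type <- match.arg(type)
  n <- length(cloud$seq_id)
  if (n < spec$motif_length) stop("chain shorter than motif_length")
  alphabet <- if (type == "alpha") spec$motif_alpha else spec$motif_beta
  with_seed(derive_seed(seed, "motif"), {
    start <- sample.int(n - spec$motif_length + 1L, 1L)
    win <- start:(start + spec$motif_length - 1L)
    cloud$labels[win] <- sample(alphabet, spec$motif_length, replace = TRUE)
    list(cloud = cloud, interface = cloud$seq_id[win])
  })
}

#' Generate a full labelled synthetic pair dataset
#'
#' Builds a population of chains, plants motifs, and assembles exactly
#' `n_pos` positive pairs (one alpha-carrier with one beta-carrier, in that
#' column order) and `n_neg` negative pairs drawn from the combinations
#' (none, none), (alpha, none), (none, beta), (alpha, alpha), (beta, beta) -
#' so interaction is a strictly pairwise property. Every protein is used in
#' exactly one pair. Structures are optionally written as PDB files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, every structure is written as
#'   `<dir>/<id>.pdb` via [write_pdb()] and a `pairs.tsv` / `truth.tsv` are
#'   emitted alongside.
#' @param null_labels If `TRUE`, keeps all structures but assigns pair labels
#'   uniformly at random (the chance-level control); the truth table still
#'   records the motif assignment.
#' @return A list of class `s2g_synth_data`: `pairs` (data frame `id1`,
#'   `id2`, `label`), `clouds` (named list of `s2g_cloud`), `truth` (data
#'   frame `id`, `motif`, `interface` comma-joined string), `interfaces`
#'   (named list of integer vectors), and `spec`.
#' @export
make_dataset <- function(spec = synthetic_spec(), dir = NULL,
                         null_labels = FALSE) {
  n_pairs <- spec$n_pos + spec$n_neg
  if (n_pairs < 1) stop("infeasible spec: no pairs requested")

  # motif assignment per negative pair, cycling through the five
  # label-uninformative combinations
  neg_combos <- list(c("none", "none"), c("alpha", "none"), c("none", "beta"),
                     c("alpha", "alpha"), c("beta", "beta"))
  motif_of <- character(2 * n_pairs)
  for (i in seq_len(spec$n_pos)) {
    motif_of[c(2 * i - 1, 2 * i)] <- c("alpha", "beta")
  }
  for (j in seq_len(spec$n_neg)) {
    i <- spec$n_pos + j
    motif_of[c(2 * i - 1, 2 * i)] <- neg_combos[[(j - 1) %% 5 + 1]]
  }

  ids <- sprintf("synth%04d", seq_len(2 * n_pairs))
  lens <- with_seed(derive_seed(spec$seed, "lengths"),
                    sample(spec$chain_length[1]:spec$chain_length[2],
                           2 * n_pairs, replace = TRUE))
  clouds <- vector("list", 2 * n_pairs)
  interfaces <- vector("list", 2 * n_pairs)
  names(clouds) <- names(interfaces) <- ids
  for (i in seq_len(2 * n_pairs)) {
    cl <- make_chain(lens[i], spec, seed = derive_seed(spec$seed, "protein", i),
                     structure_id = ids[i])
    if (motif_of[i] != "none") {
      pm <- plant_motif(cl, motif_of[i], spec,
                        seed = derive_seed(spec$seed, "plant", i))
      cl <- pm$cloud
      interfaces[[i]] <- pm$interface
    } else {
      interfaces[[i]] <- integer(0)
    }
    clouds[[i]] <- cl
  }

  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  if (null_labels) {
    labels <- with_seed(derive_seed(spec$seed, "null-labels"),
                        sample(c(0L, 1L), n_pairs, replace = TRUE))
  }
  pairs <- data.frame(
    id1 = ids[2 * seq_len(n_pairs) - 1],
    id2 = ids[2 * seq_len(n_pairs)],
    label = labels,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = ids, motif = motif_of,
    interface = vapply(interfaces, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in ids) write_pdb(clouds[[id]], file.path(dir, paste0(id, ".pdb")))
    write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  structure(list(pairs = pairs, clouds = clouds, truth = truth,
                 interfaces = interfaces, spec = spec),
            class = "s2g_synth_data")
}

#' @export
print.s2g_synth_data <- function(x, ...) {
  cat("<s2g_synth_data> ", nrow(x$pairs), " pairs (",
      sum(x$pairs$label == 1), " positive), ", length(x$clouds),
      " structures\n", sep = "")
  invisible(x)
}

#' Build contact graphs for every structure of a synthetic dataset
#'
#' @param data An `s2g_synth_data`.
#' @param cfg A [graph_config()].
#' @return A named list of `s2g_graph` objects.
#' @export
dataset_graphs <- function(data, cfg = graph_config()) {
  lapply(data$clouds, build_graph, cfg = cfg)
}
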