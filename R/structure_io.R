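# Reading and writing residue-level protein structures.
#
# Parsing is delegated to bio3d; this layer applies the selection policies the
# classifier assumes: single chain, first MODEL only, heavy atoms of standard
# (or mappable) residues, altloc conflicts resolved by occupancy.

# Nonstandard residues mapped to their standard parents; anything else
# becomes "X" (kept, so graph geometry stays intact).
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.AA_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
                MLY = "LYS", KCX = "LYS", FME = "MET", CME = "CYS")

map_residue_label <- function(resid) {
  resid <- toupper(resid)
  out <- ifelse(resid %in% .AA3, resid,
                ifelse(resid %in% names(.AA_PARENT), .AA_PARENT[resid], "X"))
  unname(out)
}

#' Parse a PDB file into a single-chain residue-level structure
#'
#' Reads `ATOM` records (plus `HETATM` records of mappable modified residues
#' such as MSE) from the first `MODEL` of a PDB file, keeps heavy atoms only,
#' resolves alternate locations by highest occupancy (ties by alphabetical
#' altloc) and returns one chain.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to select. If `NULL` (default), the chain
#'   with the most resolved residues is chosen (ties by alphabetical chain id).
#' @param structure_id Identifier for the structure; defaults to the file name
#'   without extension.
#' @param on_degenerate What to do with residues that lose every atom to
#'   filtering (e.g. hydrogen-only residues): `"skip"` drops them with a
#'   warning (default), `"fail"` raises an error.
#' @return An object of class `s2g_structure`: a list with `structure_id`,
#'   `chain_id`, `atoms` (a data frame with one row per retained atom:
#'   `serial`, `name`, `altloc`, `element`, `occupancy`, `resid`, `seq_id`,
#'   `icode`, `x`, `y`, `z`) and `source_path`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' cl <- make_chain(5, synthetic_spec(), seed = 1)
#' write_pdb(cl, pdb)
#' s <- parse_pdb(pdb)
#' coarse_grain(s)
#' @seealso [coarse_grain()], [write_pdb()]
#' @export
parse_pdb <- function(path, chain = NULL, structure_id = NULL,
                      on_degenerate = c("skip", "fail")) {
  on_degenerate <- match.arg(on_degenerate)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1

  # heavy atoms of standard residues, plus mappable modified residues
  keep_het <- at$type == "HETATM" & toupper(at$resid) %in% names(.AA_PARENT)
  at <- at[at$type == "ATOM" | keep_het, , drop = FALSE]
  before <- unique(paste(at$chain, at$resno, at$insert))
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no residues after filtering in ", path)
  lost <- setdiff(before, unique(paste(at$chain, at$resno, at$insert)))
  if (length(lost)) {
    if (identical(on_degenerate, "fail")) {
      stop("degenerate residue (no retained heavy atoms): ",
           paste(lost, collapse = "; "))
    }
    warning("degenerate residue skipped (no retained heavy atoms): ",
            paste(lost, collapse = "; "))
  }

  # chain selection: requested chain, or the chain with most residues
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop("chain not found: '", chain, "' in ", path)
    at <- at[at$chain == chain, , drop = FALSE]
  } else {
    rid <- paste(at$chain, at$resno, at$insert)
    counts <- tapply(rid, at$chain, function(z) length(unique(z)))
    chains <- names(counts)[order(-counts, names(counts))]
    chain <- chains[1]
    at <- at[at$chain == chain, , drop = FALSE]
  }

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties broken by alphabetically first altloc
  at$..rid <- paste(at$resno, at$insert, sep = "|")
  key <- paste(at$..rid, at$elety, sep = "@")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$..rid, at$elety, sep = "@")), , drop = FALSE]
  # restore file order
  at <- at[order(at$eleno), , drop = FALSE]

  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy))
  atoms <- data.frame(
    serial    = at$eleno,
    name      = at$elety,
    altloc    = at$alt,
    element   = elem,
    occupancy = at$o,
    resid     = map_residue_label(at$resid),
    seq_id    = at$resno,
    icode     = at$insert,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (nrow(atoms) == 0) stop("empty structure: chain '", chain, "' has no residues")

  structure(
    list(structure_id = structure_id, chain_id = chain, atoms = atoms,
         source_path = path),
    class = "s2g_structure"
  )
}

#' Coarse-grain a structure to residue centroids
#'
#' Each residue is replaced by the unweighted arithmetic mean of its retained
#' heavy-atom coordinates; occupancy is ignored once alternate locations have
#' been resolved. Residue order, identifiers and labels follow file order.
#'
#' @param s An `s2g_structure` from [parse_pdb()].
#' @return An object of class `s2g_cloud`: a list with `structure_id`,
#'   `chain_id`, `seq_id` (integer vector), `icode` (character vector),
#'   `labels` (3-letter amino-acid codes, "X" for unknown) and `centroids`
#'   (an N x 3 matrix, Angstrom).
#' @export
coarse_grain <- function(s) {
  stopifnot(inherits(s, "s2g_structure"))
  at <- s$atoms
  rid <- paste(at$seq_id, at$icode, sep = "|")
  idx <- split(seq_len(nrow(at)), factor(rid, levels = unique(rid)))
  centroids <- t(vapply(idx, function(i)
    c(mean(at$x[i]), mean(at$y[i]), mean(at$z[i])), numeric(3)))
  first <- vapply(idx, `[`, integer(1), 1L)
  cloud <- structure(
    list(structure_id = s$structure_id,
         chain_id = s$chain_id,
         seq_id = at$seq_id[first],
         icode = at$icode[first],
         labels = at$resid[first],
         centroids = unname(centroids)),
    class = "s2g_cloud"
  )
  validate_cloud(cloud)
  cloud
}

validate_cloud <- function(cloud) {
  n <- length(cloud$seq_id)
  stopifnot(n >= 1,
            length(cloud$icode) == n,
            length(cloud$labels) == n,
            is.matrix(cloud$centroids),
            nrow(cloud$centroids) == n,
            ncol(cloud$centroids) == 3,
            all(is.finite(cloud$centroids)))
  invisible(cloud)
}

# Construct a cloud directly (used by the synthetic generator).
new_cloud <- function(structure_id, seq_id, labels, centroids,
                      chain_id = "A", icode = NULL) {
  cloud <- structure(
    list(structure_id = structure_id, chain_id = chain_id,
         seq_id = as.integer(seq_id),
         icode = icode %||% rep("", length(seq_id)),
         labels = labels, centroids = unname(as.matrix(centroids))),
    class = "s2g_cloud"
  )
  validate_cloud(cloud)
  cloud
}

#' @export
print.s2g_cloud <- function(x, ...) {
  cat("<s2g_cloud> ", x$structure_id, " chain ", x$chain_id, ": ",
      length(x$seq_id), " residues\n", sep = "")
  invisible(x)
}

#' Write a residue cloud as a PDB file
#'
#' Emits one CA `ATOM` record per residue (coordinates to 3 decimals) so that
#' synthetic structures and coarse-grained clouds round-trip exactly through
#' [parse_pdb()] + [coarse_grain()].
#'
#' @param cloud An `s2g_cloud`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(cloud, path) {
  validate_cloud(cloud)
  n <- length(cloud$seq_id)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(cloud$centroids)),
    eleno = seq_len(n),
    elety = rep("CA", n),
    resid = cloud$labels,
    chain = rep(cloud$chain_id, n),
    resno = cloud$seq_id,
    insert = cloud$icode,
    o = rep(1, n), b = rep(0, n),
    elesy = rep("C", n)
  )
  invisible(path)
}

#' Convert a cloud to a data frame
#'
#' @param x An `s2g_cloud`.
#' @param ... Unused.
#' @return A data frame with columns `structure_id`, `chain`, `seq_id`,
#'   `icode`, `aa`, `x`, `y`, `z`.
#' @export
as.data.frame.s2g_cloud <- function(x, ...) {
  data.frame(structure_id = x$structure_id, chain = x$chain_id,
             seq_id = x$seq_id, icode = x$icode, aa = x$labels,
             x = x$centroids[, 1], y = x$centroids[, 2], z = x$centroids[, 3],
             stringsAsFactors = FALSE)
}
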