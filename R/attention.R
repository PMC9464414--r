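# Residue-importance profiles from the knowledge-selection probabilities, and
# their scoring against interface annotations and variant classes.

#' Residue-importance profile from a pair prediction
#'
#' Flags the `ceil(fraction * N)` residues with the highest knowledge-selection
#' probability as important. Ties at the cutoff are broken by ascending
#' residue sequence number, so the flag set is deterministic and invariant to
#' internal storage order.
#'
#' @param pred An `s2g_prediction` from [predict_pair()].
#' @param which Which protein of the pair: 1 or 2.
#' @param fraction Flagging fraction in (0, 1] (default 0.2, the top 20%).
#' @return A data frame of class `s2g_profile` with columns `structure_id`,
#'   `seq_id`, `icode`, `aa`, `p`, `rank` (1 = highest p), `flagged`.
#' @export
importance_profile <- function(pred, which = 1L, fraction = 0.2) {
  stopifnot(inherits(pred, "s2g_prediction"), which %in% c(1L, 2L))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  g <- pred$graphs[[which]]
  if (is.null(g)) stop("prediction carries no graph metadata; use predict_pair()")
  p <- if (which == 1L) pred$attention$p1 else pred$attention$p2
  n <- length(p)
  k <- ceiling(fraction * n)
  ord <- order(-p, g$seq_id, g$icode)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  out <- data.frame(
    structure_id = g$structure_id,
    seq_id = g$seq_id, icode = g$icode, aa = g$labels,
    p = p, rank = rank, flagged = rank <= k,
    stringsAsFactors = FALSE
  )
  class(out) <- c("s2g_profile", "data.frame")
  out
}

#' Residue-level confusion of flagged residues against an interface annotation
#'
#' @param profile An `s2g_profile`.
#' @param annotated_seq_ids Integer sequence numbers of literature interface
#'   residues. Ids not present in the profile are reported in `unknown_ids`
#'   (and excluded from the counts), never silently dropped.
#' @return A list of class `s2g_residue_confusion`: `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`, `accuracy`, `unknown_ids`. Sensitivity is
#'   `NA` when the annotation is empty.
#' @export
interface_confusion <- function(profile, annotated_seq_ids) {
  stopifnot(inherits(profile, "s2g_profile"))
  unknown <- setdiff(annotated_seq_ids, profile$seq_id)
  if (length(unknown)) {
    warning("annotated residues not in structure: ",
            paste(unknown, collapse = ", "))
  }
  ann <- profile$seq_id %in% annotated_seq_ids
  fl <- profile$flagged
  TP <- sum(fl & ann); FP <- sum(fl & !ann)
  FN <- sum(!fl & ann); TN <- sum(!fl & !ann)
  structure(
    list(TP = TP, FP = FP, FN = FN, TN = TN,
         sensitivity = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
         specificity = if (TN + FP == 0) NA_real_ else TN / (TN + FP),
         accuracy = (TP + TN) / length(fl),
         unknown_ids = unknown),
    class = "s2g_residue_confusion"
  )
}

#' Enrichment of variant classes among important residues
#'
#' For a set of profiles and a variant table, reports the fraction of
#' disease variants falling on flagged (important) residues and the fraction
#' of polymorphisms falling on unflagged residues. Variants that cannot be
#' resolved to a profiled residue are listed and excluded from denominators.
#'
#' @param profiles A list of `s2g_profile` objects (one per structure).
#' @param variants Data frame with columns `structure_id`, `seq_id`, `class`
#'   (`"disease"` or `"polymorphism"`).
#' @return A list with `disease_important_fraction`,
#'   `polymorphism_unimportant_fraction`, counts `n_disease` /
#'   `n_polymorphism` (resolved variants), and `unresolved` (data frame of
#'   variants that matched no profiled residue).
#' @export
variant_enrichment <- function(profiles, variants) {
  stopifnot(all(c("structure_id", "seq_id", "class") %in% names(variants)),
            all(variants$class %in% c("disease", "polymorphism")))
  prof_by_id <- do.call(rbind, lapply(profiles, function(p) {
    as.data.frame(p)[c("structure_id", "seq_id", "flagged")]
  }))
  flag_of <- function(sid, rid) {
    hit <- prof_by_id$flagged[prof_by_id$structure_id == sid &
                                prof_by_id$seq_id == rid]
    if (length(hit) == 0) NA else any(hit)
  }
  flags <- mapply(flag_of, variants$structure_id, variants$seq_id)
  unresolved <- variants[is.na(flags), , drop = FALSE]
  res <- variants[!is.na(flags), , drop = FALSE]
  fl <- flags[!is.na(flags)]
  dis <- res$class == "disease"
  pol <- res$class == "polymorphism"
  list(
    disease_important_fraction =
      if (sum(dis) == 0) NA_real_ else mean(fl[dis]),
    polymorphism_unimportant_fraction =
      if (sum(pol) == 0) NA_real_ else mean(!fl[pol]),
    n_disease = sum(dis), n_polymorphism = sum(pol),
    unresolved = unresolved
  )
}
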