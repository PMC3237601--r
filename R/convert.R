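#' Convert a pair score matrix to single-residue scores
#'
#' Each residue is assigned the highest pair-wise score of any pair it
#' participates in: ligand residues take their row maximum, receptor
#' residues their column maximum.
#'
#' @param scores Numeric ligand x receptor score matrix.
#' @return list(ligand, receptor) of per-residue scores (named when the
#'   matrix has dimnames).
#' @export
pairs_to_single <- function(scores) {
  scores <- as.matrix(scores)
  if (!length(scores)) stop("empty score matrix")
  list(ligand = apply(scores, 1L, max), receptor = apply(scores, 2L, max))
}

#' Convert single-residue scores to a pair score matrix
#'
#' The pair-wise score of a residue pair is the mean of the two residues'
#' individual scores — the conversion used to benchmark partner-unaware
#' predictors on the pair task.
#'
#' @param scores_ligand,scores_receptor Numeric per-residue score vectors.
#' @return Matrix with entry (a, b) = (scores_ligand[a] +
#'   scores_receptor[b]) / 2.
#' @export
single_to_pairs <- function(scores_ligand, scores_receptor) {
  if (!length(scores_ligand) || !length(scores_receptor)) {
    stop("both score vectors must be non-empty")
  }
  outer(as.numeric(scores_ligand), as.numeric(scores_receptor), `+`) / 2
}

#' Partner-specific interface predictions for one chain
#'
#' Predicts the target chain's interface against each of several candidate
#' partner chains (pair prediction followed by [pairs_to_single()] on the
#' target side) and flags residues that rank in the top-k against two or
#' more partners as "common" (partner-unspecific) predictions, which can be
#' removed to display the partner-specific sites.
#'
#' @param model A pair-trained [train_ensemble()] model.
#' @param target Target chain: list(chain = [new_chain()] or residue vector,
#'   pssm = `pssm_profile` or matrix).
#' @param partners List of two or more partner chains in the same format.
#' @param top_k Number of top-scoring residues considered per partner
#'   (default 30); truncated to the chain length.
#' @return data.frame with columns partner, idx, aa, score, rank, top_k,
#'   common — one block of target-chain rows per partner.
#' @export
partner_specific_sites <- function(model, target, partners, top_k = 30) {
  stopifnot(inherits(model, "pair_ensemble"), model$mode == "pair")
  if (length(partners) < 2L) stop("at least two partner chains are required")
  as_chain <- function(x, id) {
    ch <- x$chain
    if (!inherits(ch, "pairsite_chain")) ch <- new_chain(id, .as_aa_vector(ch))
    ch
  }
  tgt <- as_chain(target, "T")
  k <- min(top_k, length(tgt))
  pnames <- names(partners)
  if (is.null(pnames)) pnames <- paste0("partner", seq_along(partners))
  per_partner <- lapply(seq_along(partners), function(p) {
    pc <- as_chain(partners[[p]], paste0("P", p))
    # dummy complex: target as ligand, partner as receptor; contacts only
    # provide the residue bookkeeping, not labels
    cx <- complex_structure(paste0("target_vs_", pnames[p]),
                            list(tgt), list(pc))
    ct <- .dummy_contacts(cx)
    entry <- list(structure = cx, contacts = ct,
                  pssms = stats::setNames(list(target$pssm, partners[[p]]$pssm),
                                          c(tgt$chain_id, pc$chain_id)))
    scores <- predict_complex(model, entry, output = "pairs")
    s <- pairs_to_single(scores)$ligand
    rk <- rank(-s, ties.method = "first")
    data.frame(partner = pnames[p], idx = seq_along(s), aa = tgt$aa,
               score = as.numeric(s), rank = rk, top_k = rk <= k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_partner)
  topcount <- tapply(out$top_k, out$idx, sum)
  out$common <- out$top_k & topcount[as.character(out$idx)] >= 2
  rownames(out) <- NULL
  out
}

# complete all-zero contact grid used when only residue bookkeeping is needed
.dummy_contacts <- function(cx) {
  lt <- .side_table(cx$ligand)
  rt <- .side_table(cx$receptor)
  grid <- expand.grid(li = seq_len(nrow(lt)), rj = seq_len(nrow(rt)),
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    complex_id = cx$complex_id,
    ligand_chain = lt$chain[grid$li], ligand_idx = lt$idx[grid$li],
    ligand_aa = lt$aa[grid$li],
    receptor_chain = rt$chain[grid$rj], receptor_idx = rt$idx[grid$rj],
    receptor_aa = rt$aa[grid$rj],
    min_dist = NA_real_, label = 0L, stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- NA_real_
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Write single-residue scores as TSV
#'
#' @param scores data.frame as returned by
#'   [predict_complex()] with `output = "single"` or
#'   [partner_specific_sites()].
#' @param file Output path.
#' @export
write_single_scores <- function(scores, file) {
  utils::write.table(scores, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
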