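#' Score one docking decoy pose by contact agreement
#'
#' The pose's contact set (its ligand x receptor pairs labelled by the same
#' 6.0 Angstrom any-atom rule) is treated as a label vector and the AUC of
#' the predicted pair scores against it is the pose score: poses whose
#' contacts coincide with high-scoring predicted pairs score near 1. A pose
#' with zero (or all) contacts is unscorable and yields NA.
#'
#' @param pair_scores Numeric ligand x receptor prediction matrix
#'   (see [predict_complex()]).
#' @param pose Pose object: list(pose_id, contacts, external_rank,
#'   native_rmsd) where contacts is a 0/1 matrix of the same dimension as
#'   `pair_scores` (or a `contact_table` over the same residues).
#' @return AUC in [0, 1], or NA when the pose is unscorable.
#' @export
score_pose <- function(pair_scores, pose) {
  lab <- pose$contacts
  if (is.data.frame(lab)) lab <- contact_matrix(lab, "label")
  lab <- as.matrix(lab)
  if (!all(dim(lab) == dim(as.matrix(pair_scores)))) {
    stop("pose contact matrix dimensions do not match the score matrix")
  }
  y <- as.integer(lab)
  if (sum(y) == 0L || sum(y) == length(y)) return(NA_real_)
  roc_auc(as.numeric(as.matrix(pair_scores)), y)$auc
}

#' Score and rank all poses of a decoy set
#'
#' @param pair_scores Prediction matrix for the complex.
#' @param decoy_set A `decoy_set` (see [generate_decoy_set()]) or plain
#'   list of poses.
#' @return data.frame with one row per pose: pose_id, auc, external_rank,
#'   rmsd; unscorable poses carry NA auc.
#' @export
score_poses <- function(pair_scores, decoy_set) {
  poses <- if (inherits(decoy_set, "decoy_set")) decoy_set$poses else decoy_set
  out <- do.call(rbind, lapply(poses, function(p) {
    data.frame(pose_id = p$pose_id, auc = score_pose(pair_scores, p),
               external_rank = p$external_rank, rmsd = p$native_rmsd,
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(out$auc))) stop("no scorable pose in the decoy set")
  rownames(out) <- NULL
  out
}

#' Rank poses by AUC score
#'
#' Descending AUC; ties (and unscorable poses, which sort last) broken by
#' pose_id for determinism.
#'
#' @param scored data.frame from [score_poses()] (columns pose_id, auc).
#' @return Input data.frame reordered, with an auc_rank column (1 = best).
#' @export
rank_poses <- function(scored) {
  ord <- order(-ifelse(is.na(scored$auc), -Inf, scored$auc), scored$pose_id)
  out <- scored[ord, , drop = FALSE]
  out$auc_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Weighted consensus of an external ranking with the AUC ranking
#'
#' Combined score of a pose = (w_ext * external_rank + w_auc * auc_rank) /
#' (w_ext + w_auc); poses are re-ranked by ascending combined score. The
#' default 3:1 weighting favours the external (energy-based) ranking, with
#' the contact-agreement AUC rank as a corrective term. Weights c(1, 0)
#' reproduce the external ranking exactly and c(0, 1) the AUC ranking.
#'
#' @param external_ranks,auc_ranks Named numeric vectors (names = pose ids)
#'   or data.frames with pose_id plus rank column; must cover the same pose
#'   set.
#' @param weights Length-2 numeric, external first (default c(3, 1)).
#' @return data.frame pose_id, external_rank, auc_rank, combined_score,
#'   consensus_rank, ordered by consensus_rank (ties by pose_id).
#' @export
consensus_rank <- function(external_ranks, auc_ranks, weights = c(3, 1)) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) stats::setNames(x[[col]], x$pose_id) else x
  }
  ext <- as_named(external_ranks, "external_rank")
  auc <- as_named(auc_ranks, "auc_rank")
  if (is.null(names(ext)) || is.null(names(auc))) {
    stop("rankings must be named by pose id")
  }
  if (!setequal(names(ext), names(auc))) {
    stop("external and AUC rankings cover different pose sets")
  }
  auc <- auc[names(ext)]
  if (length(weights) != 2L || sum(weights) <= 0) {
    stop("weights must be two non-negative numbers with a positive sum")
  }
  combined <- (weights[1] * ext + weights[2] * auc) / sum(weights)
  ord <- order(combined, names(ext))
  out <- data.frame(pose_id = names(ext)[ord], external_rank = ext[ord],
                    auc_rank = auc[ord], combined_score = combined[ord],
                    stringsAsFactors = FALSE)
  out$consensus_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count native-like hits in the top of a ranking
#'
#' @param ranking data.frame with pose_id in ranked order (e.g. from
#'   [rank_poses()] or [consensus_rank()]), or a character vector of pose
#'   ids in ranked order.
#' @param rmsd_metadata Named numeric vector of native/decoy RMSD values
#'   (Angstrom) covering every pose in the ranking.
#' @param top_n Number of top-ranked poses considered (default 2000).
#' @param rmsd_cutoff A pose is native-like when rmsd < cutoff
#'   (default 2.5).
#' @return Integer hit count.
#' @export
count_hits <- function(ranking, rmsd_metadata, top_n = 2000, rmsd_cutoff = 2.5) {
  ids <- if (is.data.frame(ranking)) ranking$pose_id else as.character(ranking)
  rmsd <- rmsd_metadata[ids]
  if (anyNA(rmsd)) {
    stop("missing RMSD for pose(s): ",
         paste(ids[is.na(rmsd)], collapse = ", "))
  }
  top <- utils::head(seq_along(ids), max(0, top_n))
  sum(rmsd[top] < rmsd_cutoff)
}

#' Write a decoy ranking report as TSV
#'
#' @param scored Ranked data.frame (from [rank_poses()] merged with
#'   consensus columns if available).
#' @param rmsd_cutoff Native-like threshold used for the is_hit column.
#' @param file Output path.
#' @export
write_decoy_report <- function(scored, file, rmsd_cutoff = 2.5) {
  scored$is_hit <- as.integer(scored$rmsd < rmsd_cutoff)
  utils::write.table(scored, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
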