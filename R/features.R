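#' Feature specification for one window-encoding model
#'
#' Each stage-1 network sees, for every residue, a sliding-window block of
#' sparse (one-hot) residue identities of width `sparse_window` and a block
#' of scaled PSSM rows of width `pssm_window` (widths 0, 1, 3, 5 or 7; 0
#' disables the block), optionally followed by the 20-dimensional global
#' amino-acid composition of the residue's chain.
#'
#' @param sparse_window,pssm_window Window widths in residues; odd, at most
#'   7, or 0 to disable. At least one must be non-zero.
#' @param use_composition Append the per-chain composition block
#'   (default TRUE).
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(sparse_window, pssm_window, use_composition = TRUE) {
  ok <- function(w) w %in% c(0L, 1L, 3L, 5L, 7L)
  sparse_window <- as.integer(sparse_window)
  pssm_window <- as.integer(pssm_window)
  if (!ok(sparse_window) || !ok(pssm_window)) {
    stop("window widths must be one of 0, 1, 3, 5, 7")
  }
  if (sparse_window == 0L && pssm_window == 0L) {
    stop("featureless specification: both windows are 0")
  }
  structure(list(sparse_window = sparse_window, pssm_window = pssm_window,
                 use_composition = isTRUE(use_composition)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("feature_spec: sparse window", x$sparse_window,
      "| PSSM window", x$pssm_window,
      if (x$use_composition) "| + chain composition" else "", "\n")
  invisible(x)
}

#' Per-residue feature vector length implied by a specification
#'
#' @param spec A [feature_spec()].
#' @return Integer length: 20 x (sparse_window + pssm_window), plus 20 when
#'   the composition block is enabled.
#' @export
feature_length <- function(spec) {
  20L * (spec$sparse_window + spec$pssm_window) +
    if (spec$use_composition) 20L else 0L
}

#' Sparse (one-hot) encoding of a residue type
#'
#' @param aa_type One-letter residue code(s).
#' @return For one code, a 20-vector with a single 1 at the alphabet
#'   position; for several codes, a length(aa) x 20 matrix.
#' @export
sparse_encode <- function(aa_type) {
  idx <- .aa_index(aa_type)
  m <- matrix(0, length(idx), 20L)
  m[cbind(seq_along(idx), idx)] <- 1
  colnames(m) <- aa_alphabet()
  if (length(idx) == 1L) drop(m) else m
}

#' Squash PSSM log-odds scores into (0, 1)
#'
#' Logistic transform 1/(1+exp(-x)); monotone, maps 0 to 0.5, and bounds
#' network inputs.
#'
#' @param log_odds Numeric log-odds score(s).
#' @return Value(s) in (0, 1).
#' @export
scale_pssm <- function(log_odds) {
  1 / (1 + exp(-log_odds))
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the ASCII matrix dialect written by PSI-BLAST (and by
#' [write_pssm()]): a column-header line naming 20 residue letters followed
#' by one row per position with the position index, the query residue and
#' at least 20 integer log-odds scores (trailing percentage/information
#' columns are ignored). Columns are reordered to [aa_alphabet()].
#'
#' @param ascii_source Path to the matrix file.
#' @param sequence Optional one-letter sequence (vector or single string) to
#'   cross-check length and residue identities against.
#' @param chain_id Identifier stored on the profile.
#' @return Object of class `pssm_profile`: list(chain_id, sequence, matrix)
#'   with an L x 20 log-odds matrix.
#' @export
read_pssm <- function(ascii_source, sequence = NULL, chain_id = NA_character_) {
  lines <- readLines(ascii_source)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(tk) {
    length(tk) >= 20L && all(tk[1:20] %in% aa_alphabet())
  }, TRUE)
  if (!any(is_header)) stop("no PSSM column header line found in ", ascii_source)
  hdr <- toks[[which(is_header)[1]]][1:20]
  col_order <- match(aa_alphabet(), hdr)
  rows <- list(); seq_aa <- character()
  for (tk in toks[seq_along(toks) > which(is_header)[1]]) {
    if (length(tk) == 0L) next
    if (is.na(suppressWarnings(as.integer(tk[1])))) break  # footer reached
    if (length(tk) < 22L) {
      stop("malformed PSSM row (", length(tk) - 2L,
           " score columns, expected 20) in ", ascii_source)
    }
    vals <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(vals)) stop("non-numeric PSSM scores in ", ascii_source)
    rows[[length(rows) + 1L]] <- vals[col_order]
    seq_aa <- c(seq_aa, tk[2])
  }
  if (!length(rows)) stop("no PSSM rows found in ", ascii_source)
  mat <- do.call(rbind, rows)
  colnames(mat) <- aa_alphabet()
  if (!is.null(sequence)) {
    sequence <- .as_aa_vector(sequence)
    if (length(sequence) != nrow(mat)) {
      stop("PSSM has ", nrow(mat), " rows but sequence has ",
           length(sequence), " residues")
    }
    if (!all(sequence == seq_aa)) {
      stop("PSSM query residues disagree with the supplied sequence")
    }
  }
  structure(list(chain_id = chain_id, sequence = seq_aa, matrix = mat),
            class = "pssm_profile")
}

#' Write a PSSM profile in PSI-BLAST ASCII format
#'
#' @param profile A `pssm_profile` (or bare L x 20 matrix plus `sequence`).
#' @param file Output path.
#' @param sequence Residue letters when `profile` is a bare matrix.
#' @export
write_pssm <- function(profile, file, sequence = NULL) {
  if (inherits(profile, "pssm_profile")) {
    mat <- profile$matrix; sequence <- profile$sequence
  } else {
    mat <- as.matrix(profile)
    if (is.null(sequence)) stop("sequence required for a bare matrix")
    sequence <- .as_aa_vector(sequence)
  }
  stopifnot(ncol(mat) == 20L, nrow(mat) == length(sequence))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("      ", paste(sprintf("%3s", aa_alphabet()), collapse = " ")), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(sprintf("%4d %s ", i, sequence[i]),
                      paste(sprintf("%3d", round(mat[i, ])), collapse = " ")), con)
  }
  invisible(file)
}

.as_aa_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  toupper(as.character(sequence))
}

#' Read protein sequences from a FASTA file
#'
#' @param file FASTA path.
#' @return Named list of one-letter residue vectors (gaps removed).
#' @export
read_sequences <- function(file) {
  aln <- bio3d::read.fasta(file)
  out <- lapply(seq_len(nrow(aln$ali)), function(i) {
    s <- toupper(aln$ali[i, ])
    s[!s %in% c("-", ".", "X")]
  })
  names(out) <- aln$id
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named list of residue vectors (or strings).
#' @param file Output path.
#' @export
write_sequences <- function(seqs, file) {
  seqs <- lapply(seqs, .as_aa_vector)
  width <- max(vapply(seqs, length, 1L))
  ali <- t(vapply(seqs, function(s) c(s, rep("-", width - length(s))),
                  character(width)))
  bio3d::write.fasta(ids = names(seqs), seqs = ali, file = file)
  invisible(file)
}

#' Window feature vector for one residue
#'
#' Concatenates the sparse one-hot window block, the logistic-scaled PSSM
#' window block and (optionally) the chain composition block for the residue
#' at `position`. In `mode = "train"`, positions where the larger window
#' half-width would overrun either terminus are excluded (returns NULL), so
#' training patterns only contain fully observed windows. In
#' `mode = "predict"`, missing neighbour slots are zero-padded so that every
#' residue receives a feature vector and downstream score matrices are
#' complete.
#'
#' @param chain A [new_chain()] object or one-letter residue vector/string.
#' @param pssm A `pssm_profile` or L x 20 log-odds matrix; may be NULL when
#'   `spec$pssm_window == 0`.
#' @param position 1-based residue index.
#' @param spec A [feature_spec()].
#' @param mode "predict" (zero-pad termini) or "train" (exclude termini).
#' @return Numeric vector of length [feature_length()] or NULL when the
#'   position is excluded in training mode.
#' @export
residue_features <- function(chain, pssm, position, spec,
                             mode = c("predict", "train")) {
  mode <- match.arg(mode)
  aa <- if (inherits(chain, "pairsite_chain")) chain$aa else .as_aa_vector(chain)
  L <- length(aa)
  if (position < 1L || position > L) stop("position out of range")
  half <- max(spec$sparse_window, spec$pssm_window)
  half <- if (half > 0L) (half - 1L) %/% 2L else 0L
  if (mode == "train" && (position - half < 1L || position + half > L)) {
    return(NULL)
  }
  sf <- .chain_feature_blocks(aa, pssm, spec)
  .features_at(sf, position, spec)
}

# Precompute per-chain matrices used by the window encoder:
#   sparse L x 20 one-hot, scaled L x 20 PSSM, 20-dim composition.
.chain_feature_blocks <- function(aa, pssm, spec) {
  L <- length(aa)
  sparse <- if (spec$sparse_window > 0L) {
    m <- matrix(0, L, 20L); m[cbind(seq_len(L), .aa_index(aa))] <- 1; m
  } else NULL
  pmat <- NULL
  if (spec$pssm_window > 0L) {
    if (is.null(pssm)) stop("spec requires a PSSM but none was supplied")
    pm <- if (inherits(pssm, "pssm_profile")) pssm$matrix else as.matrix(pssm)
    if (nrow(pm) != L) stop("PSSM rows (", nrow(pm), ") != chain length (", L, ")")
    pmat <- scale_pssm(pm)
  }
  comp <- if (spec$use_composition) {
    as.numeric(table(factor(aa, levels = aa_alphabet()))) / L
  } else NULL
  list(L = L, sparse = sparse, pssm = pmat, comp = comp)
}

# Assemble the feature vector at one position from precomputed blocks,
# zero-padding out-of-range window slots.
.features_at <- function(blocks, position, spec) {
  take <- function(mat, width) {
    if (width == 0L) return(numeric(0))
    half <- (width - 1L) %/% 2L
    pos <- position + (-half):half
    out <- matrix(0, width, 20L)
    inside <- pos >= 1L & pos <= blocks$L
    out[inside, ] <- mat[pos[inside], , drop = FALSE]
    as.vector(t(out))
  }
  c(take(blocks$sparse, spec$sparse_window),
    take(blocks$pssm, spec$pssm_window),
    blocks$comp)
}

#' Order-duplicated pair patterns for a residue pair
#'
#' Concatenates the two residues' feature vectors in both orders (i,j) and
#' (j,i), each carrying the same binary target, so a trained network can
#' learn that pair patterns are order-independent.
#'
#' @param features_i,features_j Equal-length numeric feature vectors.
#' @param label Binary target (0/1).
#' @return List of two `pair_pattern` objects, each a list(values, target).
#' @export
pair_patterns <- function(features_i, features_j, label) {
  if (length(features_i) != length(features_j)) {
    stop("feature vectors must have equal length")
  }
  mk <- function(v) structure(list(values = v, target = as.integer(label)),
                              class = "pair_pattern")
  list(mk(c(features_i, features_j)), mk(c(features_j, features_i)))
}
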