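#' Build a protein chain record
#'
#' A chain holds the one-letter sequence of its standard residues, one
#' coordinate matrix per residue (any-atom representation), and the author
#' residue numbering from the source file. Residues are indexed 1..L in
#' observed order, decoupled from author numbering, so that sliding-window
#' arithmetic sees a gap-free sequence.
#'
#' @param chain_id Single character chain identifier.
#' @param aa Character vector of one-letter residue codes.
#' @param atoms List of numeric matrices (n_atoms x 3, Angstrom), one per
#'   residue; each must have at least one atom.
#' @param author_resno Optional integer vector of author residue numbers
#'   (defaults to 1..L).
#' @return An object of class `pairsite_chain`.
#' @export
new_chain <- function(chain_id, aa, atoms = NULL, author_resno = NULL) {
  aa <- toupper(as.character(aa))
  .aa_index(aa)  # validates the alphabet
  L <- length(aa)
  if (L == 0L) stop("chain ", chain_id, " has zero standard residues")
  if (is.null(atoms)) atoms <- rep(list(matrix(NA_real_, 0, 3)), L)
  if (length(atoms) != L) stop("atoms list length must equal sequence length")
  atoms <- lapply(atoms, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("atom coordinates must be n x 3")
    storage.mode(m) <- "double"
    m
  })
  if (is.null(author_resno)) author_resno <- seq_len(L)
  structure(
    list(chain_id = as.character(chain_id), aa = aa, atoms = atoms,
         author_resno = author_resno),
    class = "pairsite_chain"
  )
}

#' @export
length.pairsite_chain <- function(x) length(x$aa)

#' Assemble a ligand/receptor complex structure
#'
#' The unit of analysis: two groups of chains (a "ligand" side and a
#' "receptor" side, following docking-benchmark convention). Either side may
#' consist of several chains; contacts within one side are never considered.
#'
#' @param complex_id Identifier for the complex.
#' @param ligand_chains,receptor_chains Lists of [new_chain()] objects
#'   (at least one per side).
#' @return Object of class `complex_structure`.
#' @export
complex_structure <- function(complex_id, ligand_chains, receptor_chains) {
  if (inherits(ligand_chains, "pairsite_chain")) ligand_chains <- list(ligand_chains)
  if (inherits(receptor_chains, "pairsite_chain")) receptor_chains <- list(receptor_chains)
  if (length(ligand_chains) < 1L || length(receptor_chains) < 1L) {
    stop("a complex needs at least one chain on each side")
  }
  ids <- c(vapply(ligand_chains, `[[`, "", "chain_id"),
           vapply(receptor_chains, `[[`, "", "chain_id"))
  if (anyDuplicated(ids)) {
    stop("chain ids must be unique within a complex: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  structure(
    list(complex_id = as.character(complex_id),
         ligand = ligand_chains, receptor = receptor_chains),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  m <- sum(vapply(x$ligand, length, 1L))
  n <- sum(vapply(x$receptor, length, 1L))
  cat("complex_structure", x$complex_id, "\n",
      " ligand:  ", length(x$ligand), "chain(s),", m, "residues\n",
      " receptor:", length(x$receptor), "chain(s),", n, "residues\n",
      " residue pairs:", m * n, "\n")
  invisible(x)
}

# flat per-residue bookkeeping for one side of a complex
.side_table <- function(chains) {
  do.call(rbind, lapply(chains, function(ch) {
    data.frame(chain = ch$chain_id, idx = seq_along(ch$aa), aa = ch$aa,
               stringsAsFactors = FALSE)
  }))
}

#' Read a bound complex from a PDB file
#'
#' Parses coordinate records (via bio3d), keeps the requested chains only,
#' drops waters, non-protein heterogens and non-standard residues (MSE, SEC
#' and PYL are mapped to their parent standard residues), keeps the first
#' alternate location, and folds insertion codes into a sequential 1-based
#' residue index per chain. Chain breaks in author numbering are reported
#' with a message; the observed residues are treated as sequence-adjacent.
#'
#' @param pdb_source Path to a PDB file.
#' @param ligand_chain_ids,receptor_chain_ids Character vectors of chain ids
#'   forming the two sides.
#' @param complex_id Identifier; defaults to the file base name.
#' @return A [complex_structure()].
#' @export
read_complex <- function(pdb_source, ligand_chain_ids, receptor_chain_ids,
                         complex_id = NULL) {
  if (is.null(complex_id)) {
    complex_id <- sub("\\.(pdb|ent)$", "", basename(pdb_source))
  }
  pdb <- bio3d::read.pdb(pdb_source)
  at <- pdb$atom
  wanted <- c(ligand_chain_ids, receptor_chain_ids)
  missing_ch <- setdiff(wanted, unique(at$chain))
  if (length(missing_ch)) {
    stop("chain(s) not present in ", pdb_source, ": ",
         paste(missing_ch, collapse = ", "))
  }
  # first altloc only
  alt_ok <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[alt_ok & at$chain %in% wanted, , drop = FALSE]

  build <- function(cid) {
    rows <- at[at$chain == cid, , drop = FALSE]
    std <- rows$resid %in% names(.AA3TO1)
    n_dropped <- length(unique(paste(rows$resno[!std], rows$insert[!std],
                                     rows$resid[!std])))
    if (n_dropped > 0L) {
      warning("chain ", cid, ": dropped ", n_dropped,
              " non-standard residue(s)", call. = FALSE)
    }
    rows <- rows[std, , drop = FALSE]
    key <- paste(rows$resno, ifelse(is.na(rows$insert), "", rows$insert))
    ukey <- unique(key)  # file order preserved
    if (length(ukey) == 0L) {
      stop("chain ", cid, " has zero standard residues")
    }
    grp <- match(key, ukey)
    aa <- unname(.AA3TO1[rows$resid[match(seq_along(ukey), grp)]])
    atoms <- lapply(seq_along(ukey), function(i) {
      unname(as.matrix(rows[grp == i, c("x", "y", "z"), drop = FALSE]))
    })
    resno <- rows$resno[match(seq_along(ukey), grp)]
    gaps <- which(diff(resno) > 1L)
    if (length(gaps)) {
      message("chain ", cid, ": ", length(gaps),
              " chain break(s) in author numbering; residues treated as adjacent")
    }
    new_chain(cid, aa, atoms, author_resno = resno)
  }

  complex_structure(complex_id,
                    lapply(ligand_chain_ids, build),
                    lapply(receptor_chain_ids, build))
}

#' Residue index map of a complex
#'
#' Emits the mapping between the internal sequential residue index used by
#' all window arithmetic and the author numbering of the source structure.
#'
#' @param cx A [complex_structure()].
#' @return data.frame with columns side, chain, idx, author_resno, aa.
#' @export
residue_map <- function(cx) {
  one <- function(side, chains) {
    do.call(rbind, lapply(chains, function(ch) {
      data.frame(side = side, chain = ch$chain_id, idx = seq_along(ch$aa),
                 author_resno = ch$author_resno, aa = ch$aa,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one("ligand", cx$ligand), one("receptor", cx$receptor))
}

#' Minimum any-atom distance between two residues
#'
#' @param res_a,res_b Numeric n x 3 atom coordinate matrices (Angstrom).
#' @return The minimum Euclidean distance over all atom pairs (symmetric in
#'   its arguments).
#' @export
min_atom_distance <- function(res_a, res_b) {
  A <- as.matrix(res_a); B <- as.matrix(res_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("residue with empty atom list")
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
    2 * (A %*% t(B))
  sqrt(max(0, min(d2)))
}

#' Label all inter-side residue pairs of a complex
#'
#' Applies the interface definition: a ligand/receptor residue pair is in
#' contact (label 1) when the distance between any atom of one residue and
#' any atom of the other is less than or equal to `cutoff`. Every pair of
#' the pooled (m1+m2+...) ligand residues against the pooled (n1+n2+...)
#' receptor residues is labelled; intra-side pairs are never considered.
#'
#' @param cx A [complex_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 6.0).
#' @return A `contact_table`: data.frame with one row per ligand x receptor
#'   residue pair and columns complex_id, ligand_chain, ligand_idx,
#'   ligand_aa, receptor_chain, receptor_idx, receptor_aa, min_dist, label.
#' @export
extract_contacts <- function(cx, cutoff = 6.0) {
  stopifnot(inherits(cx, "complex_structure"))
  lt <- .side_table(cx$ligand)
  rt <- .side_table(cx$receptor)
  lat <- do.call(c, lapply(cx$ligand, `[[`, "atoms"))
  rat <- do.call(c, lapply(cx$receptor, `[[`, "atoms"))
  m <- nrow(lt); n <- nrow(rt)
  dmin <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) dmin[i, j] <- min_atom_distance(lat[[i]], rat[[j]])
  }
  grid <- expand.grid(li = seq_len(m), rj = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    complex_id = cx$complex_id,
    ligand_chain = lt$chain[grid$li], ligand_idx = lt$idx[grid$li],
    ligand_aa = lt$aa[grid$li],
    receptor_chain = rt$chain[grid$rj], receptor_idx = rt$idx[grid$rj],
    receptor_aa = rt$aa[grid$rj],
    min_dist = dmin[cbind(grid$li, grid$rj)],
    stringsAsFactors = FALSE
  )
  out$label <- as.integer(out$min_dist <= cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "dims") <- c(m = m, n = n)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Pool pair labels into per-residue interface labels
#'
#' A residue (on either side) is an interface residue when it participates
#' in at least one positive pair. Ligand and receptor residues of the
#' complex are pooled into one list, mirroring the single-residue view of
#' the same contact data.
#'
#' @param contacts A `contact_table` from [extract_contacts()].
#' @return data.frame with columns side, chain, idx, aa, label covering all
#'   ligand plus receptor residues.
#' @export
pool_single_residue_labels <- function(contacts) {
  stopifnot(is.data.frame(contacts))
  lkey <- paste(contacts$ligand_chain, contacts$ligand_idx)
  rkey <- paste(contacts$receptor_chain, contacts$receptor_idx)
  lig <- contacts[!duplicated(lkey), c("ligand_chain", "ligand_idx", "ligand_aa")]
  rec <- contacts[!duplicated(rkey), c("receptor_chain", "receptor_idx", "receptor_aa")]
  llab <- tapply(contacts$label, lkey, max)[paste(lig$ligand_chain, lig$ligand_idx)]
  rlab <- tapply(contacts$label, rkey, max)[paste(rec$receptor_chain, rec$receptor_idx)]
  out <- rbind(
    data.frame(side = "ligand", chain = lig$ligand_chain, idx = lig$ligand_idx,
               aa = lig$ligand_aa, label = as.integer(llab),
               stringsAsFactors = FALSE),
    data.frame(side = "receptor", chain = rec$receptor_chain, idx = rec$receptor_idx,
               aa = rec$receptor_aa, label = as.integer(rlab),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Contact labels as a ligand x receptor matrix
#'
#' @param contacts A `contact_table`.
#' @param value Column to spread ("label" or "min_dist").
#' @return Numeric matrix with ligand residues as rows ("chain:idx" names)
#'   and receptor residues as columns.
#' @export
contact_matrix <- function(contacts, value = c("label", "min_dist")) {
  value <- match.arg(value)
  lkey <- paste0(contacts$ligand_chain, ":", contacts$ligand_idx)
  rkey <- paste0(contacts$receptor_chain, ":", contacts$receptor_idx)
  lk <- unique(lkey); rk <- unique(rkey)
  m <- matrix(NA_real_, length(lk), length(rk), dimnames = list(lk, rk))
  m[cbind(match(lkey, lk), match(rkey, rk))] <- contacts[[value]]
  m
}

#' Write a contact table as TSV
#'
#' @param contacts A `contact_table`.
#' @param file Output path.
#' @export
write_contacts <- function(contacts, file) {
  utils::write.table(as.data.frame(contacts), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a contact table written by [write_contacts()]
#'
#' @param file TSV path.
#' @param cutoff Cutoff recorded on the returned object (Angstrom).
#' @return A `contact_table` data.frame.
#' @export
read_contacts <- function(file, cutoff = 6.0) {
  out <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = list(ligand_chain = "character",
                                             receptor_chain = "character"))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", "data.frame")
  out
}
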