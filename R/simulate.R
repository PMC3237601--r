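#' Configuration for the synthetic benchmark generator
#'
#' Defines the statistical structure of a generated benchmark: how many
#' complexes, chain geometry, interface size, the planted residue-type
#' pairing preferences (the signal the pair-wise models are meant to learn),
#' PSSM signal/noise, and a background noise level.
#'
#' Defaults plant a strong preference on six complementary residue-type
#' pairings with disjoint types (salt bridges D-R and E-K, aromatics W-Y,
#' hydrophobic/aromatic F-M, amide polar N-Q, hydroxyl S-T) so that the
#' contact signal lives in the pair identity rather than in single-residue
#' identity — the regime that separates partner-aware from partner-unaware
#' prediction. The multiplier is deliberately larger than the 2-4 fold
#' enrichments seen in real interface surveys: at toy benchmark sizes
#' (tens of complexes, tens of contacts each) it is what makes roughly
#' three quarters of contacts carry the planted pairing signal.
#'
#' @param n_complexes Number of complexes (default 24).
#' @param chains_per_side Range of chains per side (default c(1, 2)).
#' @param chain_length Range of residues per chain (default c(16, 24), so
#'   the largest default interface always fits on one chain).
#' @param interface_size Range of planted contact pairs per complex
#'   (default c(8, 14)).
#' @param pair_preference Named numeric vector of enrichment multipliers for
#'   unordered type pairs ("X-Y" names); unlisted pairs have weight 1.
#' @param pssm_signal Log-odds bonus of the true residue in generated PSSMs.
#' @param pssm_noise Gaussian noise s.d. on generated PSSM scores.
#' @param noise Fraction of contacts drawn ignoring the preferences
#'   (default 0.1).
#' @param seed Mandatory base seed; every fixture is a pure function of
#'   (config, seed).
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(n_complexes = 24,
                           chains_per_side = c(1, 2),
                           chain_length = c(16, 24),
                           interface_size = c(8, 14),
                           pair_preference = c("D-R" = 150, "E-K" = 150,
                                               "W-Y" = 150, "F-M" = 150,
                                               "N-Q" = 150, "S-T" = 150),
                           pssm_signal = 7, pssm_noise = 2,
                           noise = 0.1, seed) {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!rng_ok(chains_per_side) || !rng_ok(chain_length) || !rng_ok(interface_size)) {
    stop("ranges must be length-2 vectors with min <= max")
  }
  if (chains_per_side[2] > 4 || chains_per_side[1] < 1) {
    stop("chains_per_side must lie in 1..4")
  }
  if (length(pair_preference) && any(pair_preference <= 0)) {
    stop("pair-preference multipliers must be positive")
  }
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  structure(list(n_complexes = as.integer(n_complexes),
                 chains_per_side = as.integer(chains_per_side),
                 chain_length = as.integer(chain_length),
                 interface_size = as.integer(interface_size),
                 pair_preference = pair_preference,
                 pssm_signal = pssm_signal, pssm_noise = pssm_noise,
                 noise = noise, seed = .check_seed(seed)),
            class = "fixture_config")
}

# 20 x 20 symmetric weight matrix from the "X-Y" multiplier map
.preference_matrix <- function(pref) {
  ab <- aa_alphabet()
  W <- matrix(1, 20, 20, dimnames = list(ab, ab))
  for (nm in names(pref)) {
    aa <- strsplit(nm, "-", fixed = TRUE)[[1]]
    i <- .aa_index(aa[1]); j <- .aa_index(aa[2])
    W[i, j] <- pref[[nm]]; W[j, i] <- pref[[nm]]
  }
  W
}

#' Generate one synthetic complex with planted contacts
#'
#' Builds a ligand/receptor complex whose chains carry uniform random
#' sequences and one dummy (CA) atom per residue, with an interface of k
#' one-to-one contact pairs selected with probability proportional to the
#' planted type-pair multipliers (a `noise` fraction is drawn uniformly
#' instead). Geometry places each contacting pair within 6.0 Angstrom
#' (about 5) and every other inter-side pair beyond 8.5, so the 6.0
#' Angstrom extractor recovers the planted table exactly.
#'
#' @param config A [fixture_config()].
#' @param seed Seed for this complex (defaults to config$seed).
#' @param complex_id Identifier (default "synth1").
#' @return list(structure = [complex_structure()], contacts = ground-truth
#'   `contact_table` (labels planted, distances unset), planted =
#'   data.frame of the contact pairs).
#' @export
generate_complex <- function(config, seed = config$seed,
                             complex_id = "synth1") {
  stopifnot(inherits(config, "fixture_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.check_seed(seed))
  ab <- aa_alphabet()
  rint <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  # single-character chain ids (PDB chain field): ligand A.., receptor E..
  make_side <- function(ids) {
    n_ch <- rint(config$chains_per_side)
    lapply(seq_len(n_ch), function(i) {
      L <- rint(config$chain_length)
      list(chain_id = ids[i], aa = sample(ab, L, replace = TRUE))
    })
  }
  lig <- make_side(c("A", "B", "C", "D"))
  rec <- make_side(c("E", "F", "G", "H"))
  lig_aa <- unlist(lapply(lig, `[[`, "aa"))
  rec_aa <- unlist(lapply(rec, `[[`, "aa"))
  m <- length(lig_aa); n <- length(rec_aa)
  k <- rint(config$interface_size)
  if (k > min(m, n)) {
    stop("infeasible interface: ", k, " one-to-one contacts requested for ",
         m, " x ", n, " residues")
  }
  W <- .preference_matrix(config$pair_preference)
  w_full <- W[cbind(rep(.aa_index(lig_aa), n),
                    rep(.aa_index(rec_aa), each = m))]
  w_full <- matrix(w_full, m, n)
  free_i <- rep(TRUE, m); free_j <- rep(TRUE, n)
  planted <- matrix(0L, m, n)
  for (t in seq_len(k)) {
    w <- w_full
    if (stats::runif(1) < config$noise) w[] <- 1
    w[!free_i, ] <- 0; w[, !free_j] <- 0
    pick <- sample.int(m * n, 1L, prob = as.numeric(w))
    i <- (pick - 1L) %% m + 1L; j <- (pick - 1L) %/% m + 1L
    planted[i, j] <- 1L
    free_i[i] <- FALSE; free_j[j] <- FALSE
  }
  # geometry: pooled ligand residue a sits at x = 10(a-1), y = 0; a receptor
  # residue matched to a sits above it at y = 5; unmatched receptor residues
  # continue the grid beyond the ligand so every unplanted pair is > 8.5 A
  jit <- function(n) stats::runif(n, -0.3, 0.3)
  lig_xyz <- cbind(10 * (seq_len(m) - 1) + jit(m), jit(m), jit(m))
  rec_xyz <- matrix(NA_real_, n, 3)
  match_of <- apply(planted, 2, function(col) {
    i <- which(col == 1L); if (length(i)) i else NA_integer_
  })
  unmatched <- which(is.na(match_of))
  rec_x_slot <- numeric(n)
  rec_x_slot[!is.na(match_of)] <- 10 * (match_of[!is.na(match_of)] - 1)
  rec_x_slot[unmatched] <- 10 * (m + seq_along(unmatched) - 1)
  rec_xyz <- cbind(rec_x_slot + jit(n), 5 + jit(n), jit(n))
  as_chains <- function(side, aa_all, xyz) {
    off <- 0L
    lapply(side, function(ch) {
      L <- length(ch$aa)
      atoms <- lapply(seq_len(L), function(r) xyz[off + r, , drop = FALSE])
      out <- new_chain(ch$chain_id, ch$aa, atoms)
      off <<- off + L
      out
    })
  }
  cx <- complex_structure(complex_id,
                         as_chains(lig, lig_aa, lig_xyz),
                         as_chains(rec, rec_aa, rec_xyz))
  lt <- .side_table(cx$ligand); rt <- .side_table(cx$receptor)
  grid <- expand.grid(li = seq_len(m), rj = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  truth <- data.frame(
    complex_id = complex_id,
    ligand_chain = lt$chain[grid$li], ligand_idx = lt$idx[grid$li],
    ligand_aa = lt$aa[grid$li],
    receptor_chain = rt$chain[grid$rj], receptor_idx = rt$idx[grid$rj],
    receptor_aa = rt$aa[grid$rj],
    min_dist = NA_real_,
    label = planted[cbind(grid$li, grid$rj)],
    stringsAsFactors = FALSE
  )
  attr(truth, "cutoff") <- 6.0
  attr(truth, "dims") <- c(m = m, n = n)
  class(truth) <- c("contact_table", "data.frame")
  pl <- which(planted == 1L, arr.ind = TRUE)
  planted_df <- data.frame(ligand_pooled = pl[, 1], receptor_pooled = pl[, 2],
                           ligand_aa = lig_aa[pl[, 1]],
                           receptor_aa = rec_aa[pl[, 2]])
  list(structure = cx, contacts = truth, planted = planted_df)
}

#' Generate a synthetic PSSM for a sequence
#'
#' Integer log-odds rows with a background of -2, Gaussian noise of s.d.
#' `noise`, and a bonus of `signal` at the true residue column, emulating a
#' conservation profile that peaks at the observed residue. With noise = 0
#' the argmax of every row is the sequence residue.
#'
#' @param sequence Residue vector or string.
#' @param signal Log-odds bonus at the true residue (default 7).
#' @param noise Gaussian noise s.d. (default 2).
#' @param seed Seed.
#' @param chain_id Identifier stored on the profile.
#' @return A `pssm_profile` (integer-valued L x 20 matrix).
#' @export
generate_pssm <- function(sequence, signal = 7, noise = 2, seed = 1,
                          chain_id = NA_character_) {
  sequence <- .as_aa_vector(sequence)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.check_seed(seed))
  L <- length(sequence)
  mat <- matrix(stats::rnorm(L * 20, mean = -2, sd = noise), L, 20)
  mat[cbind(seq_len(L), .aa_index(sequence))] <-
    mat[cbind(seq_len(L), .aa_index(sequence))] + signal
  mat <- round(mat)
  colnames(mat) <- aa_alphabet()
  structure(list(chain_id = chain_id, sequence = sequence, matrix = mat),
            class = "pssm_profile")
}

#' Generate a full synthetic benchmark
#'
#' Produces `config$n_complexes` complexes with planted contacts plus one
#' synthetic PSSM per chain — the complete input set for training and
#' leave-one-out evaluation. Complex c uses seed config$seed + c; its
#' chains' PSSMs use seed config$seed + 1000 * c + chain index.
#'
#' @param config A [fixture_config()].
#' @return List of benchmark entries list(structure, contacts, pssms,
#'   planted), class `pair_benchmark`.
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  out <- lapply(seq_len(config$n_complexes), function(c_i) {
    g <- generate_complex(config, seed = config$seed + c_i,
                          complex_id = sprintf("synth%03d", c_i))
    chains <- c(g$structure$ligand, g$structure$receptor)
    pssms <- lapply(seq_along(chains), function(ch_i) {
      generate_pssm(chains[[ch_i]]$aa, signal = config$pssm_signal,
                    noise = config$pssm_noise,
                    seed = config$seed + 1000L * c_i + ch_i,
                    chain_id = chains[[ch_i]]$chain_id)
    })
    names(pssms) <- vapply(chains, `[[`, "", "chain_id")
    c(g, list(pssms = pssms))
  })
  class(out) <- c("pair_benchmark", "list")
  out
}

#' Generate a synthetic docking decoy set for a complex
#'
#' Emulates a rigid-body decoy resource: `n_near` near-native poses whose
#' contact sets equal the true interface (RMSD drawn below 2.5 Angstrom)
#' and shuffled decoys whose interfaces are random one-to-one matchings of
#' the same size (RMSD 3-30 Angstrom). External ranks come from a noisy
#' RMSD-based score, so they correlate with nativeness at a level set by
#' `rank_noise`.
#'
#' @param entry Benchmark entry (or list(structure, contacts)).
#' @param n_poses Total poses (>= 2).
#' @param n_near Number of near-native poses (default 1).
#' @param rank_noise S.d. of the noise on the external (pseudo-energy)
#'   score, in RMSD units (default 5).
#' @param seed Seed.
#' @return Object of class `decoy_set`: list(complex_id, poses, rmsd) where
#'   each pose is list(pose_id, contacts (0/1 matrix), external_rank,
#'   native_rmsd).
#' @export
generate_decoy_set <- function(entry, n_poses = 50, n_near = 1,
                               rank_noise = 5, seed = 1) {
  if (n_poses < 2) stop("a decoy set needs at least 2 poses")
  if (n_near < 1 || n_near >= n_poses) stop("need 1 <= n_near < n_poses")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.check_seed(seed))
  truth <- contact_matrix(entry$contacts, "label")
  m <- nrow(truth); n <- ncol(truth)
  k <- sum(truth)
  if (k == 0) stop("cannot build decoys for a complex with no contacts")
  poses <- vector("list", n_poses)
  rmsd <- numeric(n_poses)
  for (p in seq_len(n_poses)) {
    near <- p <= n_near
    if (near) {
      contacts <- truth
      rmsd[p] <- stats::runif(1, 0.5, 2.0)
    } else {
      contacts <- matrix(0L, m, n, dimnames = dimnames(truth))
      i <- sample.int(m, k); j <- sample.int(n, k)
      contacts[cbind(i, j)] <- 1L
      rmsd[p] <- stats::runif(1, 3, 30)
    }
    poses[[p]] <- list(pose_id = sprintf("pose%04d", p), contacts = contacts,
                       external_rank = NA_integer_, native_rmsd = rmsd[p])
  }
  ext_score <- rmsd + stats::rnorm(n_poses, 0, rank_noise)
  ext_rank <- rank(ext_score, ties.method = "first")  # low pseudo-energy first
  for (p in seq_len(n_poses)) poses[[p]]$external_rank <- as.integer(ext_rank[p])
  ids <- vapply(poses, `[[`, "", "pose_id")
  structure(list(complex_id = entry$contacts$complex_id[1], poses = poses,
                 rmsd = stats::setNames(rmsd, ids)),
            class = "decoy_set")
}

#' Write a benchmark to disk in standard formats
#'
#' Per complex: a PDB file, one FASTA with all chains, one PSI-BLAST ASCII
#' PSSM per chain, the ground-truth contact table as TSV, and a manifest
#' TSV describing chains and sides — the exact dialects the package
#' readers consume.
#'
#' @param benchmark Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (complex_id, chain, side,
#'   length, pdb, fasta, pssm, contacts paths).
#' @export
write_fixtures <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (entry in benchmark) {
    cx <- entry$structure
    cid <- cx$complex_id
    pdb_file <- file.path(dir, paste0(cid, ".pdb"))
    .write_pdb_complex(cx, pdb_file)
    chains <- c(cx$ligand, cx$receptor)
    sides <- rep(c("ligand", "receptor"),
                 c(length(cx$ligand), length(cx$receptor)))
    seqs <- lapply(chains, `[[`, "aa")
    names(seqs) <- paste0(cid, "_", vapply(chains, `[[`, "", "chain_id"))
    fasta_file <- file.path(dir, paste0(cid, ".fasta"))
    write_sequences(seqs, fasta_file)
    ct_file <- file.path(dir, paste0(cid, "_contacts.tsv"))
    write_contacts(entry$contacts, ct_file)
    for (ch_i in seq_along(chains)) {
      ch <- chains[[ch_i]]
      pssm_file <- file.path(dir, paste0(cid, "_", ch$chain_id, ".pssm"))
      write_pssm(entry$pssms[[ch$chain_id]], pssm_file)
      manifest[[length(manifest) + 1L]] <- data.frame(
        complex_id = cid, chain = ch$chain_id, side = sides[ch_i],
        length = length(ch), pdb = basename(pdb_file),
        fasta = basename(fasta_file), pssm = basename(pssm_file),
        contacts = basename(ct_file), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# one CA atom per residue, chains in ligand-then-receptor order
.write_pdb_complex <- function(cx, file) {
  chains <- c(cx$ligand, cx$receptor)
  xyz <- c(); resno <- c(); chain <- c(); resid <- c()
  for (ch in chains) {
    for (r in seq_along(ch$aa)) {
      at <- ch$atoms[[r]]
      for (a in seq_len(nrow(at))) {
        xyz <- c(xyz, at[a, ])
        resno <- c(resno, r)
        chain <- c(chain, ch$chain_id)
        resid <- c(resid, unname(.AA1TO3[ch$aa[r]]))
      }
    }
  }
  n_at <- length(resno)
  bio3d::write.pdb(file = file, xyz = as.numeric(xyz), resno = resno,
                   chain = chain, resid = resid,
                   elety = rep("CA", n_at), eleno = seq_len(n_at))
  invisible(file)
}

#' Read a benchmark back from a fixtures directory
#'
#' Counterpart of [write_fixtures()]: reads the manifest, PDBs, contact
#' tables and PSSMs into benchmark entries.
#'
#' @param dir Directory written by [write_fixtures()].
#' @return A `pair_benchmark` list.
#' @export
read_fixtures <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                colClasses = list(chain = "character"))
  out <- lapply(split(manifest, manifest$complex_id), function(mf) {
    mf <- mf[order(match(mf$side, c("ligand", "receptor"))), ]
    cx <- read_complex(file.path(dir, mf$pdb[1]),
                       ligand_chain_ids = mf$chain[mf$side == "ligand"],
                       receptor_chain_ids = mf$chain[mf$side == "receptor"],
                       complex_id = mf$complex_id[1])
    contacts <- read_contacts(file.path(dir, mf$contacts[1]))
    pssms <- lapply(seq_len(nrow(mf)), function(i) {
      ch <- c(cx$ligand, cx$receptor)[[
        match(mf$chain[i], vapply(c(cx$ligand, cx$receptor), `[[`, "", "chain_id"))]]
      read_pssm(file.path(dir, mf$pssm[i]), sequence = ch$aa,
                chain_id = mf$chain[i])
    })
    names(pssms) <- mf$chain
    list(structure = cx, contacts = contacts, pssms = pssms)
  })
  out <- out[order(names(out))]
  names(out) <- NULL
  class(out) <- c("pair_benchmark", "list")
  out
}
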