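#' Network hyper-parameters for stage-1 models
#'
#' @param hidden_units Hidden-layer size (single hidden layer, logistic
#'   activations; default 5).
#' @param learning_rate Nominal learning rate; retained in run metadata for
#'   completeness but not used by the quasi-Newton fit (see Details).
#' @param epochs Maximum number of training cycles (optimizer iterations).
#' @param loss "mse" (least squares on 0/1 targets, default) or "entropy"
#'   (cross-entropy).
#' @param decay Weight decay (default 0).
#'
#' @details Stage-1 networks are single-hidden-layer feedforward networks
#' with logistic output, fit by \code{nnet::nnet}. The BFGS optimizer used
#' there may converge before `epochs` iterations; `epochs` is therefore an
#' upper bound on the training cycles.
#' @return Object of class `network_params`.
#' @export
network_params <- function(hidden_units = 5, learning_rate = 0.01,
                           epochs = 100, loss = c("mse", "entropy"),
                           decay = 0) {
  loss <- match.arg(loss)
  if (epochs <= 0) stop("epochs must be positive")
  if (hidden_units < 1) stop("at least one hidden unit is required")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), loss = loss, decay = decay),
            class = "network_params")
}

#' The 24-model feature grid
#'
#' All combinations of sparse and PSSM window widths in {0, 1, 3, 5, 7},
#' excluding the featureless (0, 0) cell: 24 specifications, in
#' deterministic row-major order (sparse varying slowest).
#'
#' @param use_composition Passed to every [feature_spec()].
#' @return List of 24 `feature_spec` objects.
#' @export
make_feature_grid <- function(use_composition = TRUE) {
  widths <- c(0L, 1L, 3L, 5L, 7L)
  grid <- expand.grid(pssm = widths, sparse = widths, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$sparse, grid$pssm), ]
  grid <- grid[!(grid$sparse == 0L & grid$pssm == 0L), ]
  lapply(seq_len(nrow(grid)), function(i) {
    feature_spec(grid$sparse[i], grid$pssm[i], use_composition)
  })
}

#' Subsample the negative class for training
#'
#' Interface data are extremely imbalanced (non-contacts outnumber contacts
#' by roughly 500:1), so training keeps every positive and only a small
#' random fraction of the negatives: min(round(fraction * N), cap) items,
#' drawn uniformly without replacement. Pair-trained models use fraction
#' 0.02; single-residue models use sqrt(0.02) (about 14%), which yields a
#' comparable effective pair coverage.
#'
#' @param negatives Vector (or data.frame) of negative items; or a single
#'   integer N, in which case sampled indices are returned.
#' @param fraction Sampling fraction in (0, 1].
#' @param cap Maximum sample size (default 1000).
#' @param rng_seed Seed making the draw reproducible.
#' @return Subsample of `negatives` (or indices when `negatives` is a
#'   count); empty, with a warning, when the pool is empty.
#' @export
sample_negatives <- function(negatives, fraction = 0.02, cap = 1000, rng_seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (cap < 1) stop("cap must be at least 1")
  rng_seed <- .check_seed(rng_seed)
  as_count <- is.numeric(negatives) && length(negatives) == 1L &&
    !is.na(negatives) && negatives == round(negatives) && negatives >= 0
  N <- if (as_count) as.integer(negatives)
       else if (is.data.frame(negatives)) nrow(negatives)
       else length(negatives)
  size <- min(round(fraction * N), cap)
  if (N == 0L) {
    warning("empty negative pool; returning an empty sample")
    idx <- integer(0)
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(rng_seed)
    idx <- sample.int(N, size)
  }
  if (as_count) return(idx)
  if (is.data.frame(negatives)) negatives[idx, , drop = FALSE] else negatives[idx]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Train one stage-1 network
#'
#' Fits a single-hidden-layer feedforward network (logistic output, targets
#' 0/1) on a pattern matrix. Deterministic given `seed`, which controls the
#' weight initialization.
#'
#' @param x Numeric pattern matrix (rows = patterns).
#' @param y Binary target vector (0/1).
#' @param spec The [feature_spec()] the patterns were built under (stored
#'   with the network).
#' @param params [network_params()].
#' @param seed Weight-initialization seed.
#' @return Object of class `stage1_net`.
#' @export
train_stage1 <- function(x, y, spec, params = network_params(), seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; need both positives and negatives")
  }
  seed <- .check_seed(seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  net <- nnet::nnet(x, y, size = params$hidden_units,
                    entropy = (params$loss == "entropy"),
                    decay = params$decay, maxit = params$epochs,
                    MaxNWts = 100000L, trace = FALSE)
  structure(list(spec = spec, net = net, params = params, seed = seed,
                 n_patterns = nrow(x), n_pos = sum(y == 1)),
            class = "stage1_net")
}

#' @export
predict.stage1_net <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$net, as.matrix(newdata)))
}

# ---- internal: feature preparation over a benchmark -------------------------

# A benchmark entry is list(structure = complex_structure,
#                           contacts = contact_table,
#                           pssms    = named list of pssm_profile by chain id)
# .prepare() precomputes, per complex and per feature spec, the pooled
# ligand/receptor feature matrices (predict mode, zero-padded termini), the
# per-spec training inclusion masks (terminal exclusion) and the label
# structures, so that leave-one-out training reuses the encoding work.
.prepare <- function(data, specs) {
  out <- lapply(data, function(entry) {
    cx <- entry$structure
    ct <- entry$contacts
    side_blocks <- function(chains) {
      lapply(chains, function(ch) {
        pssm <- entry$pssms[[ch$chain_id]]
        list(aa = ch$aa,
             blocks = .chain_feature_blocks_all(ch$aa, pssm))
      })
    }
    lb <- side_blocks(cx$ligand)
    rb <- side_blocks(cx$receptor)
    per_spec <- lapply(specs, function(sp) {
      list(lig = .pool_spec_features(lb, sp),
           rec = .pool_spec_features(rb, sp),
           lig_ok = .pool_train_mask(lb, sp),
           rec_ok = .pool_train_mask(rb, sp))
    })
    labels <- contact_matrix(ct, "label")
    singles <- pool_single_residue_labels(ct)
    list(complex_id = cx$complex_id, per_spec = per_spec,
         pair_labels = labels,
         single_labels = singles$label,
         m = nrow(labels), n = ncol(labels))
  })
  structure(out, pairsite_prepared = TRUE)
}

# blocks for the maximal encoding (sparse + pssm + composition); individual
# specs slice what they need
.chain_feature_blocks_all <- function(aa, pssm) {
  L <- length(aa)
  sparse <- matrix(0, L, 20L)
  sparse[cbind(seq_len(L), .aa_index(aa))] <- 1
  pmat <- NULL
  if (!is.null(pssm)) {
    pm <- if (inherits(pssm, "pssm_profile")) pssm$matrix else as.matrix(pssm)
    if (nrow(pm) != L) stop("PSSM rows != chain length")
    pmat <- scale_pssm(pm)
  }
  comp <- as.numeric(table(factor(aa, levels = aa_alphabet()))) / L
  list(L = L, sparse = sparse, pssm = pmat, comp = comp)
}

.shift_rows <- function(mat, o) {
  L <- nrow(mat)
  out <- matrix(0, L, ncol(mat))
  src <- seq_len(L) + o
  ok <- src >= 1L & src <= L
  out[ok, ] <- mat[src[ok], , drop = FALSE]
  out
}

# L x feature_length matrix for one chain under one spec
.chain_spec_matrix <- function(blocks, spec) {
  L <- blocks$L
  parts <- list()
  if (spec$sparse_window > 0L) {
    half <- (spec$sparse_window - 1L) %/% 2L
    parts <- c(parts, lapply((-half):half, function(o) .shift_rows(blocks$sparse, o)))
  }
  if (spec$pssm_window > 0L) {
    if (is.null(blocks$pssm)) stop("spec requires a PSSM but none was supplied")
    half <- (spec$pssm_window - 1L) %/% 2L
    parts <- c(parts, lapply((-half):half, function(o) .shift_rows(blocks$pssm, o)))
  }
  if (spec$use_composition) {
    parts <- c(parts, list(matrix(blocks$comp, L, 20L, byrow = TRUE)))
  }
  do.call(cbind, parts)
}

.pool_spec_features <- function(side, spec) {
  do.call(rbind, lapply(side, function(ch) .chain_spec_matrix(ch$blocks, spec)))
}

# TRUE where a position's largest window lies fully inside its chain
.pool_train_mask <- function(side, spec) {
  half <- max(spec$sparse_window, spec$pssm_window)
  half <- if (half > 0L) (half - 1L) %/% 2L else 0L
  do.call(c, lapply(side, function(ch) {
    L <- ch$blocks$L
    ok <- rep(TRUE, L)
    if (half > 0L) ok <- seq_len(L) > half & seq_len(L) <= L - half
    ok
  }))
}

#' Train the two-stage ensemble
#'
#' Trains the 24 stage-1 networks over the feature grid, each on its own
#' reproducible negative subsample ([sample_negatives()]; seed = base_seed +
#' grid index), keeping all positives. In `mode = "pair"` the training items
#' are ligand x receptor residue pairs encoded in both orders; in
#' `mode = "single"` they are pooled individual residues with partner
#' information discarded. Positions whose window overruns a chain terminus
#' are excluded from training patterns. The stage-2 prediction is the
#' unweighted average of the 24 stage-1 outputs.
#'
#' @param data List of benchmark entries, each
#'   list(structure, contacts, pssms) (see [generate_benchmark()]).
#' @param params [network_params()].
#' @param base_seed Base seed; all stochastic steps derive their seeds from
#'   it.
#' @param mode "pair" (partner-aware) or "single" (partner-unaware).
#' @param specs Feature grid (default [make_feature_grid()]).
#' @param fraction Negative sampling fraction; defaults to 0.02 for pair
#'   mode and sqrt(0.02) for single mode.
#' @param cap Negative sample cap (default 1000).
#' @return Object of class `pair_ensemble`.
#' @export
train_ensemble <- function(data, params = network_params(), base_seed = 1,
                           mode = c("pair", "single"),
                           specs = make_feature_grid(), fraction = NULL,
                           cap = 1000) {
  mode <- match.arg(mode)
  if (is.null(fraction)) fraction <- if (mode == "pair") 0.02 else sqrt(0.02)
  base_seed <- .check_seed(base_seed)
  prepared <- if (isTRUE(attr(data, "pairsite_prepared"))) data
              else .prepare(data, specs)
  nets <- lapply(seq_along(specs), function(k) {
    tr <- .training_patterns(prepared, k, mode, fraction, cap,
                             sample_seed = base_seed + k)
    train_stage1(tr$x, tr$y, specs[[k]], params, seed = base_seed + 500L + k)
  })
  structure(list(mode = mode, specs = specs, nets = nets, params = params,
                 base_seed = base_seed, fraction = fraction, cap = cap),
            class = "pair_ensemble")
}

#' @export
print.pair_ensemble <- function(x, ...) {
  cat("pair_ensemble:", length(x$nets), "stage-1 networks,",
      sprintf("%s-trained", x$mode),
      "| negative fraction", signif(x$fraction, 4), "cap", x$cap, "\n")
  invisible(x)
}

# Assemble the training matrix for grid cell k.
.training_patterns <- function(prepared, k, mode, fraction, cap, sample_seed) {
  if (mode == "pair") {
    pieces <- lapply(prepared, function(e) {
      f <- e$per_spec[[k]]
      ok <- outer(f$lig_ok, f$rec_ok, `&`)
      idx <- which(ok, arr.ind = TRUE)
      list(i = idx[, 1], j = idx[, 2], y = e$pair_labels[idx], e = e, f = f)
    })
    y_all <- unlist(lapply(pieces, `[[`, "y"))
    pos <- which(y_all == 1L)
    neg <- which(y_all == 0L)
    keep <- sort(c(pos, neg[sample_negatives(length(neg), fraction, cap,
                                             rng_seed = sample_seed)]))
    sizes <- vapply(pieces, function(p) length(p$y), 1L)
    owner <- rep(seq_along(pieces), sizes)
    offset <- cumsum(c(0L, sizes))
    rows <- lapply(seq_along(pieces), function(ci) {
      sel <- keep[owner[keep] == ci] - offset[ci]
      if (!length(sel)) return(NULL)
      p <- pieces[[ci]]
      fi <- p$f$lig[p$i[sel], , drop = FALSE]
      fj <- p$f$rec[p$j[sel], , drop = FALSE]
      list(x = rbind(cbind(fi, fj), cbind(fj, fi)),
           y = rep(p$y[sel], 2L))
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    list(x = do.call(rbind, lapply(rows, `[[`, "x")),
         y = unlist(lapply(rows, `[[`, "y")))
  } else {
    pieces <- lapply(prepared, function(e) {
      f <- e$per_spec[[k]]
      ok <- c(f$lig_ok, f$rec_ok)
      list(x = rbind(f$lig, f$rec)[ok, , drop = FALSE],
           y = e$single_labels[ok])
    })
    x_all <- do.call(rbind, lapply(pieces, `[[`, "x"))
    y_all <- unlist(lapply(pieces, `[[`, "y"))
    pos <- which(y_all == 1L)
    neg <- which(y_all == 0L)
    keep <- sort(c(pos, neg[sample_negatives(length(neg), fraction, cap,
                                             rng_seed = sample_seed)]))
    list(x = x_all[keep, , drop = FALSE], y = y_all[keep])
  }
}

#' Stage-2 score for one residue pair
#'
#' Evaluates every stage-1 network on the pair pattern in both orders and
#' returns the mean of all 2 x 24 outputs: the average over the two orders,
#' averaged over the grid. Exactly symmetric under swapping the two
#' residues.
#'
#' @param model A pair-trained [train_ensemble()] model.
#' @param features_i,features_j Per-residue features: either a list with one
#'   vector per grid spec (in `model$specs` order) or, when all specs share
#'   one length, a single vector used for every spec.
#' @return Scalar score in [0, 1].
#' @export
predict_pair <- function(model, features_i, features_j) {
  stopifnot(inherits(model, "pair_ensemble"), model$mode == "pair")
  get_f <- function(f, k) if (is.list(f)) f[[k]] else f
  s <- vapply(seq_along(model$nets), function(k) {
    fi <- get_f(features_i, k); fj <- get_f(features_j, k)
    if (length(fi) != length(fj)) stop("feature vectors must have equal length")
    p <- predict(model$nets[[k]], rbind(c(fi, fj), c(fj, fi)))
    mean(p)
  }, 1.0)
  mean(s)
}

#' Score every ligand x receptor pair of a complex
#'
#' Computes the complete stage-2 score matrix for one complex. Every residue
#' receives features (termini zero-padded), so the matrix has no gaps. For a
#' single-trained model the native output is one score per pooled residue;
#' `output = "pairs"` converts via [single_to_pairs()], and for a
#' pair-trained model `output = "single"` converts via [pairs_to_single()].
#'
#' @param model A [train_ensemble()] model (either mode).
#' @param entry Benchmark entry list(structure, contacts, pssms) or an
#'   object prepared internally.
#' @param output "pairs" (default) or "single".
#' @return For "pairs": an m x n score matrix in [0, 1] with "chain:idx"
#'   dimnames. For "single": data.frame side, chain, idx, aa, score.
#' @export
predict_complex <- function(model, entry, output = c("pairs", "single")) {
  output <- match.arg(output)
  prepared <- if (!is.null(entry$per_spec)) entry
              else .prepare(list(entry), model$specs)[[1]]
  m <- prepared$m; n <- prepared$n
  if (model$mode == "pair") {
    acc <- matrix(0, m, n)
    ij <- expand.grid(i = seq_len(m), j = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    for (k in seq_along(model$nets)) {
      f <- prepared$per_spec[[k]]
      fi <- f$lig[ij$i, , drop = FALSE]
      fj <- f$rec[ij$j, , drop = FALSE]
      p1 <- predict(model$nets[[k]], cbind(fi, fj))
      p2 <- predict(model$nets[[k]], cbind(fj, fi))
      acc <- acc + matrix((p1 + p2) / 2, m, n)
    }
    scores <- acc / length(model$nets)
    dimnames(scores) <- dimnames(prepared$pair_labels)
    if (output == "pairs") return(scores)
    return(.single_from_matrix(scores, prepared))
  }
  # single-trained model: one score per pooled residue
  acc <- numeric(m + n)
  for (k in seq_along(model$nets)) {
    f <- prepared$per_spec[[k]]
    acc <- acc + predict(model$nets[[k]], rbind(f$lig, f$rec))
  }
  s <- acc / length(model$nets)
  if (output == "single") {
    out <- .residue_frame(prepared)
    out$score <- s
    return(out)
  }
  scores <- single_to_pairs(s[seq_len(m)], s[m + seq_len(n)])
  dimnames(scores) <- dimnames(prepared$pair_labels)
  scores
}

.residue_frame <- function(prepared) {
  lk <- rownames(prepared$pair_labels)
  rk <- colnames(prepared$pair_labels)
  split2 <- function(keys, side) {
    sp <- strsplit(keys, ":", fixed = TRUE)
    data.frame(side = side,
               chain = vapply(sp, `[[`, "", 1L),
               idx = as.integer(vapply(sp, `[[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  rbind(split2(lk, "ligand"), split2(rk, "receptor"))
}

.single_from_matrix <- function(scores, prepared) {
  conv <- pairs_to_single(scores)
  out <- .residue_frame(prepared)
  out$score <- c(conv$ligand, conv$receptor)
  out
}

#' Save / load a trained ensemble
#'
#' Serializes the model (specs, fitted weights, hyper-parameters and seeds)
#' to a versioned single-file archive.
#'
#' @param model A `pair_ensemble`.
#' @param file Path to write/read.
#' @return `load_ensemble` returns the restored `pair_ensemble`.
#' @export
save_ensemble <- function(model, file) {
  stopifnot(inherits(model, "pair_ensemble"))
  obj <- list(format = "pairsite_ensemble", version = 1L, model = model)
  saveRDS(obj, file)
  invisible(file)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "pairsite_ensemble")) {
    stop("not a pairsite ensemble archive: ", file)
  }
  obj$model
}
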