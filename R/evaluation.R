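#' Confusion counts at a score threshold
#'
#' Predictions are positive when score >= threshold (fixed convention).
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Decision threshold.
#' @return list(TP, FP, TN, FN); counts partition the data.
#' @export
confusion_at <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) stop("scores and labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- scores >= threshold
  list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
       TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Threshold metrics from confusion counts
#'
#' recall (sensitivity) = TP/(TP+FN); precision = TP/(TP+FP);
#' specificity = TN/(TN+FP); F1 = harmonic mean of precision and recall.
#' Ratios with zero denominators are NA; F1 is 0 when precision and recall
#' are both 0 (and NA only if a ratio is undefined while the other is not
#' informative).
#'
#' @param counts list(TP, FP, TN, FN) from [confusion_at()].
#' @return list(recall, precision, specificity, f1).
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    specificity <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall)) {
      if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    } else if (identical(TP, 0L) || TP == 0) 0 else NA_real_
    list(recall = recall, precision = precision,
         specificity = specificity, f1 = f1)
  })
}

#' ROC curve and tie-aware AUC
#'
#' The AUC is computed from the Mann-Whitney rank statistic with ties
#' counted as 1/2, so a constant predictor scores exactly 0.5; it equals
#' the trapezoidal area under the ROC curve (recall against
#' 1 - specificity) swept over all distinct thresholds.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return Object of class `roc_curve`: list(points = data.frame(threshold,
#'   fpr, recall), auc).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels length mismatch")
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fp / nneg), recall = c(0, tp / npos))
  structure(list(points = points, auc = auc, n_pos = npos, n_neg = nneg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Operating point with the highest F1
#'
#' Sweeps every distinct score as a threshold (prediction positive at
#' score >= threshold) and returns the one maximizing F1; ties resolved in
#' favour of the lowest threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes present).
#' @return list(threshold, precision, recall, f1).
#' @export
best_f1_point <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L || npos == length(labels)) {
    stop("best F1 undefined: labels contain a single class")
  }
  thr <- sort(unique(scores))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # at threshold t: predictions = items with score >= t
  tp <- vapply(thr, function(t) sum(y[s >= t]), 1)
  np <- vapply(thr, function(t) sum(s >= t), 1)
  precision <- ifelse(np > 0, tp / np, NA_real_)
  recall <- tp / npos
  f1 <- ifelse(!is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  best <- which.max(f1)  # which.max takes the first (lowest threshold) on ties
  list(threshold = thr[best], precision = precision[best],
       recall = recall[best], f1 = f1[best])
}

#' Average per-complex metrics
#'
#' Unweighted mean over complexes, the aggregation used for leave-one-out
#' results (one value per left-out complex). NA entries (complexes where
#' the metric was undefined) are dropped with a warning.
#'
#' @param per_complex_values Numeric vector of per-complex metric values.
#' @return Mean value; per-complex input retained unchanged by the caller.
#' @export
aggregate_per_complex <- function(per_complex_values) {
  if (!length(per_complex_values)) stop("no per-complex values to aggregate")
  if (anyNA(per_complex_values)) {
    warning(sum(is.na(per_complex_values)),
            " complex(es) with undefined metric dropped from the average")
  }
  mean(per_complex_values, na.rm = TRUE)
}

#' Paired comparison of two models over complexes
#'
#' Two-sided paired Student's t-test on per-complex metric values from two
#' models evaluated on the same complexes. When the paired differences have
#' zero variance the test is degenerate: p = 1 when all differences are 0,
#' otherwise NA with `degenerate = TRUE`.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2) of paired
#'   per-complex values.
#' @return list(statistic, df, p_value, mean_difference, degenerate).
#' @export
paired_model_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired vectors length mismatch")
  ok <- !(is.na(values_a) | is.na(values_b))
  d <- (values_a - values_b)[ok]
  n <- length(d)
  if (n < 2L) stop("need at least two complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(statistic = if (all(d == 0)) 0 else NaN, df = n - 1L,
                p_value = if (all(d == 0)) 1 else NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(statistic = t_stat, df = n - 1L,
       p_value = 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Leave-one-out evaluation of an ensemble over a benchmark
#'
#' For each complex: train a full ensemble on all other complexes, predict
#' the held-out complex, and measure per-complex AUC for both the pair task
#' (all ligand x receptor pairs) and the single-residue task (pooled
#' residues of both sides). Pair-trained models are converted to single
#' scores via [pairs_to_single()]; single-trained models to pair scores via
#' [single_to_pairs()]. No sampling is applied to the held-out data.
#' Complexes whose held-out labels contain a single class get NA AUC and
#' are excluded from averages with a warning.
#'
#' @param data List of benchmark entries (see [generate_benchmark()]).
#' @param params [network_params()].
#' @param base_seed Base seed; cycle c uses base_seed + 1000 * c.
#' @param mode "pair" or "single" training.
#' @param specs Feature grid.
#' @param verbose Print one line per cycle.
#' @return data.frame with one row per complex: complex_id, n_pairs,
#'   n_pos_pairs, auc_pair, auc_single, best_f1_pair; attribute "summary"
#'   holds the averaged metrics.
#' @export
loo_evaluate <- function(data, params = network_params(), base_seed = 1,
                         mode = c("pair", "single"),
                         specs = make_feature_grid(), verbose = FALSE) {
  mode <- match.arg(mode)
  base_seed <- .check_seed(base_seed)
  prepared <- if (isTRUE(attr(data, "pairsite_prepared"))) data
              else .prepare(data, specs)
  rows <- lapply(seq_along(prepared), function(ci) {
    train <- structure(prepared[-ci], pairsite_prepared = TRUE)
    model <- train_ensemble(train, params = params,
                            base_seed = base_seed + 1000L * ci,
                            mode = mode, specs = specs)
    held <- prepared[[ci]]
    scores <- predict_complex(model, held, output = "pairs")
    y_pair <- as.integer(held$pair_labels)
    y_single <- held$single_labels
    s_single <- if (model$mode == "pair") {
      conv <- pairs_to_single(scores); c(conv$ligand, conv$receptor)
    } else {
      predict_complex(model, held, output = "single")$score
    }
    two_class <- function(y) length(unique(y)) == 2L
    auc_pair <- if (two_class(y_pair)) roc_auc(as.numeric(scores), y_pair)$auc else NA_real_
    auc_single <- if (two_class(y_single)) roc_auc(s_single, y_single)$auc else NA_real_
    f1 <- if (two_class(y_pair)) best_f1_point(as.numeric(scores), y_pair)$f1 else NA_real_
    if (verbose) {
      message(sprintf("[loo %s] %s: pair AUC %.3f, single AUC %.3f",
                      mode, held$complex_id, auc_pair, auc_single))
    }
    data.frame(complex_id = held$complex_id,
               n_pairs = length(y_pair), n_pos_pairs = sum(y_pair),
               auc_pair = auc_pair, auc_single = auc_single,
               best_f1_pair = f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    mode = mode,
    mean_auc_pair = aggregate_per_complex(out$auc_pair),
    mean_auc_single = aggregate_per_complex(out$auc_single),
    mean_best_f1_pair = aggregate_per_complex(out$best_f1_pair)
  )
  out
}

#' Leave-one-out comparison of pair-trained and single-trained models
#'
#' Runs [loo_evaluate()] in both training modes on the same benchmark and
#' compares per-complex AUCs with the paired t-test, for both the pair task
#' and the single-residue task.
#'
#' @inheritParams loo_evaluate
#' @return list(pair = per-complex results of the pair-trained model,
#'   single = same for the single-trained model, tests = list of
#'   [paired_model_test()] results for auc_pair and auc_single,
#'   summary = data.frame of mean AUCs by model and task).
#' @export
loo_compare <- function(data, params = network_params(), base_seed = 1,
                        specs = make_feature_grid(), verbose = FALSE) {
  prepared <- if (isTRUE(attr(data, "pairsite_prepared"))) data
              else .prepare(data, specs)
  res_pair <- loo_evaluate(prepared, params, base_seed, mode = "pair",
                           specs = specs, verbose = verbose)
  res_single <- loo_evaluate(prepared, params, base_seed, mode = "single",
                             specs = specs, verbose = verbose)
  tests <- list(
    auc_pair = paired_model_test(res_pair$auc_pair, res_single$auc_pair),
    auc_single = paired_model_test(res_pair$auc_single, res_single$auc_single)
  )
  summary <- data.frame(
    task = c("pair", "single"),
    paired_training = c(aggregate_per_complex(res_pair$auc_pair),
                        aggregate_per_complex(res_pair$auc_single)),
    unpaired_training = c(aggregate_per_complex(res_single$auc_pair),
                          aggregate_per_complex(res_single$auc_single)),
    p_value = c(tests$auc_pair$p_value, tests$auc_single$p_value)
  )
  list(pair = res_pair, single = res_single, tests = tests, summary = summary)
}
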