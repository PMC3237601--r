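test_that("confusion counts partition the data at any threshold", {
  cc <- confusion_at(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(cc, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  cc0 <- confusion_at(c(0.9, 0.1, 0.4), c(1, 0, 0), 0)
  expect_equal(cc0$FP, 2L)  # threshold 0: everything predicted positive
  expect_equal(cc0$TN + cc0$FN, 0L)
  set.seed(11)
  s <- runif(200); y <- rbinom(200, 1, 0.3)
  for (t in c(0.2, 0.5, 0.8)) {
    cc <- confusion_at(s, y, t)
    brute <- c(TP = sum(s >= t & y == 1), FP = sum(s >= t & y == 0),
               TN = sum(s < t & y == 0), FN = sum(s < t & y == 1))
    expect_equal(unlist(cc)[names(brute)], brute)
    expect_equal(sum(unlist(cc)), 200)
  }
  expect_error(confusion_at(s, y[-1], 0.5), "mismatch")
})

test_that("threshold metrics follow their definitions with degenerate guards", {
  m <- classification_metrics(list(TP = 5, FP = 5, FN = 5, TN = 85))
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$f1, 0.5)
  perfect <- classification_metrics(list(TP = 10, FP = 0, FN = 0, TN = 90))
  expect_equal(unlist(perfect[c("recall", "precision", "specificity", "f1")]),
               c(recall = 1, precision = 1, specificity = 1, f1 = 1))
  degen <- classification_metrics(list(TP = 0, FP = 4, FN = 6, TN = 90))
  expect_equal(degen$precision, 0)
  expect_equal(degen$f1, 0)
})

test_that("tie-aware AUC equals the brute-force Mann-Whitney count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "single class")
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:300, 1)
    s <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, bruteforce_auc(s, y), tolerance = 1e-12)
  }
})

test_that("ROC curve spans (0,0) to (1,1) and integrates to the rank AUC", {
  set.seed(14)
  s <- round(runif(150), 2); y <- rbinom(150, 1, 0.3)
  rc <- roc_auc(s, y)
  pts <- rc$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$recall[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$recall[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$recall) >= 0))
  trap <- sum(diff(pts$fpr) * (head(pts$recall, -1) + tail(pts$recall, -1)) / 2)
  expect_equal(trap, rc$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(15)
  s <- runif(100); y <- rbinom(100, 1, 0.5)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(plogis(5 * s - 2), y)$auc, a)
  expect_equal(roc_auc(rank(s), y)$auc, a)
  expect_equal(roc_auc(-s, y)$auc, 1 - a)
})

test_that("best-F1 point matches an exhaustive threshold sweep", {
  sep <- best_f1_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$f1, 1.0)
  const <- best_f1_point(rep(0.5, 8), c(1, 0, 0, 0, 1, 0, 0, 0))
  # constant scores: the only operating point predicts everything positive
  expect_equal(const$recall, 1)
  expect_equal(const$precision, 0.25)
  set.seed(16)
  s <- round(runif(120), 2); y <- rbinom(120, 1, 0.25)
  got <- best_f1_point(s, y)
  brute <- max(vapply(sort(unique(s)), function(t) {
    m <- classification_metrics(confusion_at(s, y, t)); m$f1 }, 1.0))
  expect_equal(got$f1, brute, tolerance = 1e-12)
})

test_that("per-complex aggregation is the unweighted mean", {
  expect_equal(aggregate_per_complex(c(0.6, 0.8)), 0.7)
  expect_equal(aggregate_per_complex(0.55), 0.55)
  set.seed(17)
  v <- runif(124)
  expect_equal(aggregate_per_complex(v), sum(v) / 124)
  expect_warning(m <- aggregate_per_complex(c(0.5, NA, 0.7)), "dropped")
  expect_equal(m, 0.6)
  expect_error(aggregate_per_complex(numeric(0)), "no per-complex")
})

test_that("paired model test matches the textbook t statistic", {
  idn <- paired_model_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$statistic, 0)
  expect_equal(idn$p_value, 1)
  expect_true(idn$degenerate)
  shift <- paired_model_test(1:10 + 0.5, 1:10)
  expect_true(shift$degenerate)  # constant difference: zero variance
  expect_true(is.na(shift$p_value))
  set.seed(18)
  a <- runif(30); b <- a + rnorm(30, 0.05, 0.1)
  got <- paired_model_test(a, b)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(got$statistic, t_ref, tolerance = 1e-12)
  expect_equal(got$p_value, t.test(a, b, paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("leave-one-out evaluation yields one row per complex plus a summary", {
  bench <- tiny_benchmark(n = 4, seed = 71)
  res <- loo_evaluate(bench, tiny_params(), base_seed = 19, mode = "pair",
                      specs = small_grid())
  expect_equal(nrow(res), 4L)
  expect_true(all(res$auc_pair >= 0 & res$auc_pair <= 1, na.rm = TRUE))
  expect_true(all(res$n_pos_pairs > 0))
  sm <- attr(res, "summary")
  expect_equal(sm$mean_auc_pair, mean(res$auc_pair, na.rm = TRUE))
  # determinism of the whole harness
  res2 <- loo_evaluate(bench, tiny_params(), base_seed = 19, mode = "pair",
                       specs = small_grid())
  expect_identical(res$auc_pair, res2$auc_pair)
})
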