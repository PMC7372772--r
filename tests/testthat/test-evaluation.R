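fake_edges <- function(n) {
  tibble::tibble(drug_id = sprintf("d%04d", seq_len(n)), cluster = 1L)
}

test_that("folds use floor-division sizing with remainder edges train-only", {
  folds <- make_folds(fake_edges(2174), n_folds = 10, seed = 61)
  expect_length(folds, 10L)
  expect_true(all(vapply(folds, function(f) nrow(f$test), 1L) == 217L))
  expect_true(all(vapply(folds, function(f) nrow(f$train), 1L) == 2174L - 217L))
  # test folds are disjoint and, with the remainder, exhaustive
  test_ids <- unlist(lapply(folds, function(f) f$test$drug_id))
  expect_equal(anyDuplicated(test_ids), 0L)
  remainder <- setdiff(fake_edges(2174)$drug_id, test_ids)
  expect_length(remainder, 4L)
  for (f in folds) expect_true(all(remainder %in% f$train$drug_id))

  # no remainder when n divides evenly
  folds2 <- make_folds(fake_edges(20), n_folds = 10, seed = 62)
  expect_true(all(vapply(folds2, function(f) nrow(f$test), 1L) == 2L))
  expect_error(make_folds(fake_edges(5), n_folds = 10), "at least")
})

test_that("negative sampling is matched, disjoint from edges, and seeded", {
  net <- generate_bipartite(30, 30, density = 0.3, seed = 63)
  negs <- sample_negatives(net, 217, ratio = 1, seed = 64)
  expect_equal(nrow(negs), 217L)
  A <- net$adjacency
  expect_true(all(A[cbind(match(negs$drug_id, net$drugs), negs$cluster)] == 0L))
  expect_identical(negs, sample_negatives(net, 217, ratio = 1, seed = 64))
  expect_false(identical(negs, sample_negatives(net, 217, ratio = 1, seed = 65)))
  expect_equal(nrow(sample_negatives(net, 10, ratio = 1.5, seed = 66)), 15L)

  dense <- make_net(matrix(1L, 3, 3))
  expect_error(sample_negatives(dense, 1), "non-interacting")
})

test_that("threshold sweep reproduces hand-computed ROC values", {
  cur <- roc_pr_curves(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0))
  expect_equal(cur$auc, 0.75)
  expect_equal(cur$roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(cur$roc$tpr, c(0, 0.5, 0.5, 1, 1))

  perfect <- roc_pr_curves(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)

  flat <- roc_pr_curves(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(flat$auc, 0.5)

  expect_error(roc_pr_curves(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("trapezoidal AUC equals the tie-corrected rank statistic", {
  withr::with_seed(67, {
    for (rep in 1:40) {
      n <- sample(5:40, 1)
      score <- sample(0:5, n, replace = TRUE) + round(runif(n), 2)
      label <- rbinom(n, 1, 0.5)
      if (sum(label) == 0 || sum(label) == n) next
      expect_equal(roc_pr_curves(score, label)$auc, oracle_auc(score, label),
                   tolerance = 1e-10)
    }
  })
})

test_that("confusion metrics follow the rate definitions with NA for undefined", {
  m <- confusion_metrics(tp = 3, fp = 2, tn = 4, fn = 1)
  expect_equal(m$tpr, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$fpr, 1 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$f1, 2 / 3)  # precision 0.6, recall 0.75
  expect_equal(confusion_metrics(tp = 4, fp = 0, tn = 2, fn = 1)$precision, 1)
  expect_true(is.na(confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 2)$precision))
})

test_that("cross-validation is reproducible and leak-free", {
  net <- generate_bipartite(25, 25, density = 0.25, seed = 68)
  cv1 <- run_cv(net, "CN", n_folds = 5, seed = 69)
  cv2 <- run_cv(net, "CN", n_folds = 5, seed = 69)
  expect_identical(cv1$metrics, cv2$metrics)
  cv3 <- run_cv(net, "CN", n_folds = 5, seed = 70)
  expect_false(identical(cv1$metrics, cv3$metrics))
  expect_equal(nrow(cv1$metrics), 5L)
  expect_true(all(cv1$metrics$auc >= 0 & cv1$metrics$auc <= 1))
  expect_true(all(cv1$metrics$aupr >= 0 & cv1$metrics$aupr <= 1))
  g <- glance(cv1)
  expect_equal(g$auc, mean(cv1$metrics$auc))

  # leak-freedom: scoring the test positives on the *full* network would be
  # optimistic; verify the reduced-network scores differ for held-out pairs
  folds <- withr::with_seed(69, make_folds(tidy(net), n_folds = 5))
  f <- folds[[1]]
  S_full <- score_all(net, "CN")$scores
  S_red <- score_all(remove_edges(net, f$test), "CN")$scores
  i <- cbind(match(f$test$drug_id, net$drugs), f$test$cluster)
  expect_true(mean(S_full[i]) > mean(S_red[i]))
})

test_that("benchmark baseline sits at chance and is reproducible", {
  net <- generate_bipartite(40, 40, density = 0.25, seed = 71)
  bl <- benchmark_baseline(net, "CN", repetitions = 25, seed = 72)
  expect_lt(abs(bl$auc - 0.5), 3 * bl$se + 0.02)
  expect_equal(bl$aucs,
               benchmark_baseline(net, "CN", repetitions = 25, seed = 72)$aucs)
  expect_equal(nrow(bl$curve), 101L)
  expect_true(all(diff(bl$curve$mean_tpr) >= -1e-12))

  # single seeded repetition is a reproducible curve
  b1 <- benchmark_baseline(net, "CN", repetitions = 1, seed = 73)
  b2 <- benchmark_baseline(net, "CN", repetitions = 1, seed = 73)
  expect_equal(b1$curve, b2$curve)

  # degree-preserving variant runs and stays near chance on an Erdos-Renyi graph
  bd <- benchmark_baseline(net, "CN", repetitions = 10, seed = 74,
                           mode = "degree_preserving")
  expect_lt(abs(bd$auc - 0.5), 0.15)
})

test_that("adjusted metrics subtract the baseline", {
  net <- generate_bipartite(20, 20, density = 0.3, seed = 75)
  cv <- run_cv(net, "PA", n_folds = 4, seed = 76)
  bl <- benchmark_baseline(net, "PA", repetitions = 10, seed = 77)
  adj <- adjust_metrics(cv, bl)
  expect_equal(adj$adjusted_auc, adj$auc - adj$baseline_auc)
})
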