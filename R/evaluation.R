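#' Partition known edges into cross-validation folds
#'
#' Edges are shuffled (seeded) and split into `n_folds` test folds of
#' exactly `floor(n / n_folds)` edges each. The remainder edges
#' (`n mod n_folds`) stay in every training set and appear in no test fold
#' -- the convention under which 2174 known pairs over 10 folds give test
#' folds of exactly 217.
#'
#' @param edges Tibble of known edges (`drug_id`, `cluster`).
#' @param n_folds Number of folds (>= 2).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of `n_folds` elements, each `list(train = tibble,
#'   test = tibble)`; test folds are pairwise disjoint and, together with
#'   the remainder, exhaust the edges.
#' @export
make_folds <- function(edges, n_folds = 10, seed = NULL) {
  edges <- as_tibble(edges)
  n <- nrow(edges)
  stopifnot(n_folds >= 2)
  if (n < n_folds) {
    abort(sprintf("need at least %d edges for %d folds, got %d", n_folds, n_folds, n))
  }
  fold_size <- n %/% n_folds
  with_seed_or_current(seed, {
    perm <- sample.int(n)
    edges <- edges[perm, , drop = FALSE]
    lapply(seq_len(n_folds), function(f) {
      idx <- seq((f - 1) * fold_size + 1, f * fold_size)
      list(train = edges[-idx, , drop = FALSE], test = edges[idx, , drop = FALSE])
    })
  })
}

#' Sample non-interacting drug-cluster pairs
#'
#' Uniform sample without replacement from the zero cells of the adjacency
#' (pairs not known to interact), matched to the positives at the given
#' ratio: `ceiling(ratio * n_positives)` negatives. Always disjoint from the
#' known edges; additional pairs can be excluded (the benchmark uses this to
#' keep its fake positives out of the negative pool).
#'
#' @param network A `dca_network`.
#' @param n_positives Number of test positives to match.
#' @param ratio Negatives per positive (> 0; default 1).
#' @param seed Optional integer seed.
#' @param exclude Optional tibble (`drug_id`, `cluster`) of extra pairs to
#'   exclude from the pool.
#' @return A tibble (`drug_id`, `cluster`) of sampled non-edges.
#' @export
sample_negatives <- function(network, n_positives, ratio = 1, seed = NULL,
                             exclude = NULL) {
  stopifnot(inherits(network, "dca_network"), ratio > 0)
  A <- network$adjacency
  zero <- which(A == 0L)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl_idx <- (match(exclude$cluster, network$clusters) - 1L) * nrow(A) +
      match(exclude$drug_id, network$drugs)
    zero <- setdiff(zero, excl_idx)
  }
  n_neg <- ceiling(ratio * n_positives)
  if (length(zero) < n_neg) {
    abort(sprintf("only %d non-interacting pairs available, need %d", length(zero), n_neg))
  }
  with_seed_or_current(seed, {
    pick <- sample(zero, n_neg)
    tibble(drug_id = network$drugs[(pick - 1L) %% nrow(A) + 1L],
           cluster = as.integer((pick - 1L) %/% nrow(A) + 1L))
  })
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Sweeps the decision threshold over the distinct observed scores (a pair
#' is called positive when its score is greater than or equal to the
#' threshold), plus a sentinel above the maximum so the curves start at the
#' origin. Equal scores share a single threshold step, which makes the
#' trapezoidal ROC area identical to the tie-corrected rank (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param score Numeric vector of prediction scores.
#' @param label Logical or 0/1 vector, `TRUE`/1 for a true interaction.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`), `pr`
#'   (tibble `threshold`, `recall`, `precision`), `auc` and `aupr`
#'   (trapezoidal areas).
#' @examples
#' roc_pr_curves(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_pr_curves <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  P <- sum(label); N <- sum(!label)
  if (P == 0 || N == 0) {
    abort("need at least one positive and one negative to sweep thresholds")
  }
  thr <- sort(unique(score), decreasing = TRUE)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; l <- label[ord]
  cum_tp <- cumsum(l); cum_fp <- cumsum(!l)
  last <- length(s) - match(thr, rev(s)) + 1L  # last index with score >= threshold
  tp <- cum_tp[last]; fp <- cum_fp[last]
  roc <- tibble(threshold = c(Inf, thr),
                fpr = c(0, fp / N), tpr = c(0, tp / P))
  prec <- tp / (tp + fp)
  pr <- tibble(threshold = c(Inf, thr),
               recall = c(0, tp / P), precision = c(prec[1], prec))
  auc <- trapezoid(roc$fpr, roc$tpr)
  aupr <- trapezoid(pr$recall, pr$precision)
  list(roc = roc, pr = pr, auc = auc, aupr = aupr)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Metrics from a confusion table
#'
#' Classification metrics at a fixed threshold. Metrics with a zero
#' denominator are reported as `NA` (undefined), never coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A one-row tibble with `tpr`, `fpr`, `sensitivity`, `specificity`,
#'   `precision`, `f1` (sensitivity = TPR = TP/(TP+FN); FPR = FP/(TN+FP);
#'   specificity = 1 - FPR).
#' @examples
#' confusion_metrics(tp = 3, fp = 2, tn = 4, fn = 1)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- safe(tp, tp + fn)
  fpr <- safe(fp, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(tpr) && (prec + tpr) > 0) {
    2 * prec * tpr / (prec + tpr)
  } else NA_real_
  tibble(tpr = tpr, fpr = fpr, sensitivity = tpr,
         specificity = if (is.na(fpr)) NA_real_ else 1 - fpr,
         precision = prec, f1 = f1)
}

# Score test pairs against a score matrix.
lookup_scores <- function(score_matrix, pairs, drugs) {
  score_matrix[cbind(match(pairs$drug_id, drugs), pairs$cluster)]
}

# Threshold sweep maximizing F1; returns the metrics row at the best
# threshold (ties -> largest threshold, i.e. the most conservative call).
max_f1_metrics <- function(score, label) {
  thr <- sort(unique(score), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    pred <- score >= t
    confusion_metrics(tp = sum(pred & label), fp = sum(pred & !label),
                      tn = sum(!pred & !label), fn = sum(!pred & label))
  })
  f1 <- vapply(rows, function(r) r$f1 %||% NA_real_, 1)
  best <- which.max(replace(f1, is.na(f1), -Inf))
  dplyr::bind_cols(tibble(threshold = thr[best]), rows[[best]])
}

#' Ten-fold cross-validated evaluation of a link-prediction index
#'
#' For each fold the test-positive edges are removed from the adjacency (so
#' the index cannot see the answer), every test pair -- the held-out
#' positives plus `negatives_per_positive` sampled non-edges -- is scored on
#' the reduced network, and ROC/PR curves are computed by threshold sweep.
#' Scalar F1 / sensitivity / specificity are reported at the threshold
#' maximizing F1 on the fold's test scores; the full curves are kept so any
#' other threshold convention can be recovered. The overall performance is
#' the fold-level average. Fully reproducible from (config, seed).
#'
#' @param network A `dca_network`.
#' @param method `"CN"`, `"JA"` or `"PA"`.
#' @param n_folds Number of folds (default 10).
#' @param negatives_per_positive Negative sampling ratio (default 1).
#' @param seed Optional integer seed covering the fold shuffle and every
#'   negative sample.
#' @return An object of class `dca_cv`: list with `metrics` (per-fold
#'   tibble: `fold`, `auc`, `aupr`, `threshold`, `f1`, `sensitivity`,
#'   `specificity`), `curves` (per-fold list of `roc`/`pr` tibbles),
#'   `method`, `config`. Use [glance()] for the fold-averaged row.
#' @examples
#' net <- generate_bipartite(20, 20, density = 0.25, seed = 3)
#' cv <- run_cv(net, "CN", n_folds = 5, seed = 42)
#' glance(cv)
#' @export
run_cv <- function(network, method = c("CN", "JA", "PA"), n_folds = 10,
                   negatives_per_positive = 1, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(network, "dca_network"))
  edges <- tidy(network)
  with_seed_or_current(seed, {
    folds <- make_folds(edges, n_folds = n_folds)
    res <- purrr::map(seq_along(folds), function(f) {
      test_pos <- folds[[f]]$test
      net_train <- remove_edges(network, test_pos)
      S <- score_all(net_train, method)$scores
      negs <- sample_negatives(network, nrow(test_pos),
                               ratio = negatives_per_positive)
      pairs <- dplyr::bind_rows(test_pos, negs)
      label <- rep(c(TRUE, FALSE), c(nrow(test_pos), nrow(negs)))
      sc <- lookup_scores(S, pairs, network$drugs)
      cur <- roc_pr_curves(sc, label)
      mx <- max_f1_metrics(sc, label)
      list(metrics = dplyr::bind_cols(
             tibble(fold = f, auc = cur$auc, aupr = cur$aupr),
             mx[c("threshold", "f1", "sensitivity", "specificity")]),
           curves = cur[c("roc", "pr")])
    })
    structure(
      list(metrics = dplyr::bind_rows(purrr::map(res, "metrics")),
           curves = purrr::map(res, "curves"),
           method = method,
           config = list(n_folds = n_folds,
                         negatives_per_positive = negatives_per_positive,
                         seed = seed)),
      class = "dca_cv")
  })
}

#' @export
print.dca_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dca_cv> %s, %d folds: AUC %.3f, AUPR %.3f, F1 %.3f\n",
              x$method, nrow(x$metrics), g$auc, g$aupr, g$f1))
  invisible(x)
}

#' @describeIn run_cv Per-fold metrics tibble.
#' @param x A `dca_cv`.
#' @param ... Unused.
#' @method tidy dca_cv
#' @export
tidy.dca_cv <- function(x, ...) x$metrics

#' @describeIn run_cv Fold-averaged metrics (one row).
#' @method glance dca_cv
#' @export
glance.dca_cv <- function(x, ...) {
  dplyr::summarise(x$metrics,
                   method = x$method[1], n_folds = dplyr::n(),
                   auc = mean(.data$auc), aupr = mean(.data$aupr),
                   f1 = mean(.data$f1, na.rm = TRUE),
                   sensitivity = mean(.data$sensitivity, na.rm = TRUE),
                   specificity = mean(.data$specificity, na.rm = TRUE))
}

#' Randomized-interaction benchmark baseline
#'
#' Estimates the chance level of an index on a given network by repeatedly
#' evaluating deliberately invalid interactions: each repetition replaces
#' the test-positive set with an equal-size random sample of non-edges,
#' keeps the matched negative sampling (negatives drawn disjointly from the
#' fake positives), scores with the index, and computes the ROC. The
#' baseline curve is the vertical average of the repetitions' ROC curves on
#' a common FPR grid, and the baseline AUC is the mean over repetitions --
#' expected near 0.5. An index's adjusted performance is its real metric
#' minus this baseline.
#'
#' `mode = "degree_preserving"` draws the fake positives with probability
#' proportional to the product of the endpoint degrees instead of
#' uniformly, preserving the degree bias of real edges.
#'
#' @param network A `dca_network`.
#' @param method `"CN"`, `"JA"` or `"PA"`.
#' @param repetitions Number of randomizations (default 100).
#' @param n_folds Used only to size the fake test set
#'   (`floor(n_edges / n_folds)`, matching the real CV fold size).
#' @param negatives_per_positive Negative sampling ratio.
#' @param seed Optional integer seed.
#' @param mode `"uniform"` (default) or `"degree_preserving"`.
#' @return A list with `auc` (mean baseline AUC), `se` (standard error over
#'   repetitions), `aucs` (per-repetition), `curve` (tibble `fpr`,
#'   `mean_tpr` on a 0..1 grid), `repetitions`, `method`.
#' @export
benchmark_baseline <- function(network, method = c("CN", "JA", "PA"),
                               repetitions = 100, n_folds = 10,
                               negatives_per_positive = 1, seed = NULL,
                               mode = c("uniform", "degree_preserving")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(network, "dca_network"), repetitions >= 1)
  A <- network$adjacency
  n_edges <- sum(A)
  test_size <- max(1L, n_edges %/% n_folds)
  # fake positives are non-edges, so removing them changes nothing: the
  # score matrix is computed once for all repetitions
  S <- score_all(network, method)$scores
  zero <- which(A == 0L)
  kx <- rowSums(A); ky <- colSums(A)
  wts <- if (mode == "degree_preserving") {
    w <- outer(kx, ky)[zero]
    if (all(w == 0)) rep(1, length(zero)) else w
  } else NULL
  grid <- seq(0, 1, by = 0.01)
  with_seed_or_current(seed, {
    reps <- purrr::map(seq_len(repetitions), function(r) {
      fake_idx <- if (is.null(wts)) sample(zero, test_size) else
        sample(zero, test_size, prob = wts)
      fake <- tibble(drug_id = network$drugs[(fake_idx - 1L) %% nrow(A) + 1L],
                     cluster = as.integer((fake_idx - 1L) %/% nrow(A) + 1L))
      negs <- sample_negatives(network, test_size,
                               ratio = negatives_per_positive, exclude = fake)
      pairs <- dplyr::bind_rows(fake, negs)
      label <- rep(c(TRUE, FALSE), c(nrow(fake), nrow(negs)))
      cur <- roc_pr_curves(lookup_scores(S, pairs, network$drugs), label)
      list(auc = cur$auc,
           tpr = approx(cur$roc$fpr, cur$roc$tpr, xout = grid,
                        ties = max, rule = 2)$y)
    })
    aucs <- purrr::map_dbl(reps, "auc")
    tprs <- do.call(rbind, purrr::map(reps, "tpr"))
    list(auc = mean(aucs),
         se = sd(aucs) / sqrt(repetitions),
         aucs = aucs,
         curve = tibble(fpr = grid, mean_tpr = colMeans(tprs)),
         repetitions = repetitions, method = method, mode = mode)
  })
}

#' Baseline-adjusted metrics
#'
#' Subtracts the benchmark baseline from cross-validated metrics, so a
#' chance-level index scores about 0.
#'
#' @param cv A `dca_cv` report.
#' @param baseline A [benchmark_baseline()] result.
#' @return One-row tibble: `auc`, `baseline_auc`, `adjusted_auc`.
#' @export
adjust_metrics <- function(cv, baseline) {
  g <- glance(cv)
  tibble(method = g$method, auc = g$auc, baseline_auc = baseline$auc,
         adjusted_auc = g$auc - baseline$auc)
}
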