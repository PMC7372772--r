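test_that("toy-graph index values match brute-force enumeration", {
  net <- toy_net()
  expect_equal(score_cn(net, "d1", 3), 1)             # {c1,c2} ∩ {c2,c3}
  expect_equal(score_jaccard(net, "d1", 3), 1 / 3)
  expect_equal(score_pa(net, "d1", 3), 2 * 1)

  # a drug with no edges scores CN 0 against every cluster
  A <- rbind(toy_net()$adjacency, d3 = c(0L, 0L, 0L))
  net3 <- make_net(A)
  for (y in 1:3) expect_equal(score_cn(net3, "d3", y), 0)

  # intersection bound
  for (y in 1:3) {
    ns <- neighbor_sets(net, "d2", y)
    expect_lte(score_cn(net, "d2", y),
               min(length(ns$gamma_drug), length(ns$gamma_hat_cluster)))
  }
})

test_that("Jaccard degenerates correctly at the boundary cases", {
  # Gamma(x) == Gamma-hat(y) non-empty -> 1: single drug, single cluster
  A <- matrix(1L, 1, 1)
  expect_equal(score_jaccard(make_net(A), "d1", 1), 1)
  # both empty -> 0 by convention
  expect_equal(score_jaccard(make_net(matrix(0L, 1, 1)), "d1", 1), 0)
})

test_that("score_all agrees elementwise with pairwise calls and the oracle", {
  net <- toy_net()
  S <- score_all(net, "CN")$scores
  for (i in 1:2) for (j in 1:3) {
    expect_equal(S[i, j], score_cn(net, net$drugs[i], j))
  }
  expect_equal(unname(S), oracle_score_matrix(net$adjacency, "CN"))

  empty <- make_net(matrix(0L, 3, 4))
  for (m in c("CN", "JA", "PA")) {
    expect_true(all(score_all(empty, m)$scores == 0))
  }
})

test_that("all three indices match the brute-force oracle on random graphs", {
  withr::with_seed(51, {
    for (rep in 1:30) {
      n <- sample(2:15, 1)
      m <- sample(2:15, 1)
      A <- matrix(rbinom(n * m, 1, runif(1, 0.1, 0.6)), n, m)
      net <- make_net(A)
      for (method in c("CN", "JA", "PA")) {
        expect_equal(unname(score_all(net, method)$scores),
                     oracle_score_matrix(A, method), tolerance = 1e-12)
      }
    }
  })
})

test_that("Jaccard is the normalized common-neighbour count", {
  net <- generate_bipartite(10, 12, density = 0.3, seed = 52)
  cn <- score_all(net, "CN")$scores
  ja <- score_all(net, "JA")$scores
  expect_true(all(ja >= 0 & ja <= 1))
  A <- net$adjacency
  hat_size <- colSums(crossprod(A) > 0)
  un <- outer(rowSums(A), rep(1, ncol(A))) +
    outer(rep(1, nrow(A)), hat_size) - cn
  expect_equal(ja[un > 0], (cn / un)[un > 0], tolerance = 1e-12)
})

test_that("adding an edge never decreases PA, nor CN at the incident drug", {
  net <- generate_bipartite(10, 10, density = 0.25, seed = 53)
  A <- net$adjacency
  zero <- which(A == 0L, arr.ind = TRUE)
  pick <- zero[1, ]
  A2 <- A
  A2[pick[1], pick[2]] <- 1L
  pa1 <- score_all(make_net(A), "PA")$scores
  pa2 <- score_all(make_net(A2), "PA")$scores
  expect_true(all(pa2 >= pa1))
  cn1 <- score_all(make_net(A), "CN")$scores
  cn2 <- score_all(make_net(A2), "CN")$scores
  expect_true(all(cn2[pick[1], ] >= cn1[pick[1], ]))
})

test_that("thresholding separates significant and important associations", {
  S <- matrix(c(0, 100, 150, 200, 410, 500), 2, 3)
  sc <- structure(list(method = "CN", scores = `dimnames<-`(S,
                         list(c("d1", "d2"), c("1", "2", "3"))),
                       known_mask = matrix(0L, 2, 3)), class = "dca_scores")
  th <- threshold_scores(sc, significant_cutoff = 143, important_fraction = 0.2)
  expect_equal(th$counts$n_significant, 4L)
  expect_equal(th$counts$n_important, 1L)
  expect_equal(th$important$score, 500)

  # cutoff above the maximum empties both sets
  th2 <- threshold_scores(sc, significant_cutoff = 600)
  expect_equal(th2$counts$n_significant, 0L)
  expect_equal(th2$counts$n_important, 0L)

  # fraction 1 makes important equal significant
  th3 <- threshold_scores(sc, significant_cutoff = 143, important_fraction = 1)
  expect_equal(th3$important, th3$significant)

  # boundary ties are all included
  S4 <- matrix(c(10, 5, 5, 5, 1, 0), 2, 3)
  sc4 <- structure(list(method = "CN", scores = `dimnames<-`(S4,
                          list(c("d1", "d2"), c("1", "2", "3"))),
                        known_mask = matrix(0L, 2, 3)), class = "dca_scores")
  th4 <- threshold_scores(sc4, significant_cutoff = 0.5,
                          important_fraction = 0.2)
  expect_equal(th4$counts$n_significant, 5L)
  # ceiling(0.2 * 5) = 1 -> boundary is the top score 10, no ties
  expect_equal(th4$important$score, 10)
  th5 <- threshold_scores(sc4, significant_cutoff = 0.5,
                          important_fraction = 0.4)
  # ceiling(0.4 * 5) = 2 -> boundary score 5, ties pull in all three 5s
  expect_equal(sort(th5$important$score), c(5, 5, 5, 10))
})

test_that("significance cutoff from fold-resampled score standard errors", {
  net <- generate_bipartite(15, 15, density = 0.3, seed = 54)
  cut <- significance_cutoff_se(net, "CN", n_folds = 5, seed = 55)
  expect_gte(cut, 0)
  expect_equal(cut, significance_cutoff_se(net, "CN", n_folds = 5, seed = 55))
})

test_that("prediction expansion walks evidence to trimer and protein candidates", {
  # cluster 2 has one member trimer found in two proteins; d2 is significant for it
  cl <- manual_clustering(c(MGN = 2L, GMG = 1L), k = 2)
  cx <- tibble::tibble(
    complex_id = c("cx1", "cx2"),
    protein_id = c("p1", "p2"),
    drug_id = c("d1", "d1"),
    site = c("NGMG", "NGM"))
  net <- build_network(cx, cl, basis_model())
  sig <- tibble::tibble(drug_id = "d2", cluster = 2L)
  # d2 is not in the network; expansion only needs evidence for the cluster
  ex <- expand_predictions(net, sig)
  expect_equal(nrow(ex$drug_trimer), 1L)
  expect_equal(ex$drug_trimer$canonical_key, "MGN")
  expect_true(ex$drug_trimer$novel)
  expect_equal(nrow(ex$drug_protein), 2L)
  expect_setequal(ex$drug_protein$protein_id, c("p1", "p2"))

  # a significant pair already backed by a known complex is not novel
  ex2 <- expand_predictions(net, tibble::tibble(drug_id = "d1", cluster = 2L))
  expect_false(any(ex2$drug_trimer$novel))
  expect_false(any(ex2$drug_protein$novel))

  # empty significant set gives empty outputs
  ex3 <- expand_predictions(net, sig[0, ])
  expect_equal(nrow(ex3$drug_trimer), 0L)
  expect_equal(nrow(ex3$drug_protein), 0L)

  # synthetic evidence-free networks are rejected
  expect_error(expand_predictions(generate_bipartite(3, 3, 0.5, seed = 56), sig),
               "evidence")
})
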