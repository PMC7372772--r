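test_that("edges arise from cluster assignments of site trimers, with evidence", {
  # NGMG -> windows NGM (key MGN) and GMG (key GMG); plant them in clusters 2 and 5
  cl <- manual_clustering(c(MGN = 2L, GMG = 5L), k = 5)
  cx <- tibble::tibble(complex_id = "cx1", protein_id = "p1", drug_id = "d",
                       site = "NGMG")
  net <- build_network(cx, cl, basis_model())
  expect_equal(tidy(net),
               tibble::tibble(drug_id = c("d", "d"), cluster = c(2L, 5L)))
  expect_equal(nrow(net$evidence), 2L)
  expect_setequal(net$evidence$canonical_key, c("MGN", "GMG"))

  # a second complex with the same drug and site adds evidence, not edges
  cx2 <- dplyr::bind_rows(cx, tibble::tibble(complex_id = "cx2",
                                             protein_id = "p2",
                                             drug_id = "d", site = "NGMG"))
  net2 <- build_network(cx2, cl, basis_model())
  expect_equal(tidy(net2), tidy(net))
  expect_equal(nrow(dplyr::filter(net2$evidence, cluster == 2)), 2L)
})

test_that("empty complex lists give an empty network", {
  cl <- manual_clustering(c(MGN = 1L), k = 3)
  net <- build_network(tibble::tibble(complex_id = character(),
                                      protein_id = character(),
                                      drug_id = character(),
                                      site = character()),
                       cl, basis_model())
  expect_equal(length(net$drugs), 0L)
  expect_equal(sum(net$adjacency), 0L)
  expect_equal(nrow(tidy(net)), 0L)
})

test_that("unseen trimers are routed to their nearest centroid", {
  v <- tibble::tibble(canonical_key = c("AAA", "WWW"),
                      V1 = c(0, 10), V2 = 0, V3 = 0, V4 = 0, V5 = 0)
  cl <- cluster_trimers(v, k = 2)
  emb <- fit_embedding(small_props(seed = 41))
  cx <- tibble::tibble(complex_id = "cx1", protein_id = "p1", drug_id = "d",
                       site = "CDE")  # key CDE, never clustered
  net <- build_network(cx, cl, emb)
  expected <- assign_trimers(cl, vectorize_trimer(emb, "CDE"))
  expect_equal(tidy(net)$cluster, expected)
})

test_that("two-hop neighborhoods follow the toy-graph enumeration", {
  net <- toy_net()
  ns <- neighbor_sets(net, "d1", 3)
  expect_equal(ns$gamma_drug, c(1L, 2L))
  expect_equal(ns$gamma_hat_cluster, c(2L, 3L))
  expect_equal(ns$k_drug, 2L)
  expect_equal(ns$k_cluster, 1L)
  expect_error(neighbor_sets(net, "nope", 1), "unknown drug")
  expect_error(neighbor_sets(net, "d1", 9), "unknown cluster")

  # isolated cluster has an empty two-hop neighborhood
  A <- matrix(0L, 2, 3)
  A[1, 1] <- 1L
  net0 <- make_net(A)
  expect_length(neighbor_sets(net0, net0$drugs[1], 3)$gamma_hat_cluster, 0L)

  # y with positive degree always belongs to its own two-hop set
  net_r <- generate_bipartite(12, 12, density = 0.3, seed = 42)
  for (y in which(colSums(net_r$adjacency) > 0)) {
    expect_true(y %in% neighbor_sets(net_r, net_r$drugs[1], y)$gamma_hat_cluster)
  }
})

test_that("degree summary matches hand counts and the handshake identity", {
  net <- toy_net()
  ds <- degree_summary(net)
  expect_equal(ds$density, 4 / 6)
  expect_equal(ds$n_edges, 4)
  expect_equal(ds$drug_degrees, tibble::tibble(degree = 2L, n = 2L))
  expect_equal(ds$cluster_degrees,
               tibble::tibble(degree = c(1L, 2L), n = c(2L, 1L)))

  empty <- make_net(matrix(0L, 3, 4))
  expect_equal(degree_summary(empty)$density, 0)

  net_r <- generate_bipartite(20, 15, density = 0.25, seed = 43)
  A <- net_r$adjacency
  expect_equal(sum(rowSums(A)), sum(colSums(A)))
  expect_equal(sum(rowSums(A)), sum(A))
})

test_that("rebuilding from the same inputs is bit-identical", {
  synth <- generate_complexes(synthetic_spec(n_drugs = 15, n_complexes = 20,
                                             n_proteins = 8), seed = 44)
  emb <- fit_embedding(small_props(seed = 45))
  v <- vectorize_trimers(extract_trimers(synth$complexes), emb)
  cl <- cluster_trimers(v, k = 15)
  n1 <- build_network(synth$complexes, cl, emb)
  n2 <- build_network(synth$complexes, cl, emb)
  expect_identical(n1$adjacency, n2$adjacency)
  expect_identical(n1$evidence, n2$evidence)
})

test_that("every edge's evidence trimers map back to that edge's cluster", {
  synth <- generate_complexes(synthetic_spec(n_drugs = 12, n_complexes = 16,
                                             n_proteins = 6), seed = 46)
  emb <- fit_embedding(small_props(seed = 47))
  v <- vectorize_trimers(extract_trimers(synth$complexes), emb)
  cl <- cluster_trimers(v, k = 12)
  net <- build_network(synth$complexes, cl, emb)
  lab <- setNames(cl$labels$cluster, cl$labels$canonical_key)
  expect_true(all(net$evidence$cluster == lab[net$evidence$canonical_key]))
  # and every adjacency 1 has evidence
  ev_edges <- unique(paste(net$evidence$drug_id, net$evidence$cluster))
  adj_edges <- paste(tidy(net)$drug_id, tidy(net)$cluster)
  expect_setequal(ev_edges, adj_edges)
})
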