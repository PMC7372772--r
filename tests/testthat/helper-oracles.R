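# Independent oracles and tiny fixtures used across the suite.
# Each oracle is a from-first-principles reimplementation, kept deliberately
# naive so it shares no code path with the package internals it checks.

# Wrap a 0/1 adjacency matrix as a network object.
make_net <- function(A) {
  drugs <- rownames(A) %||% sprintf("d%d", seq_len(nrow(A)))
  rownames(A) <- drugs
  colnames(A) <- as.character(seq_len(ncol(A)))
  dcanet:::new_dca_network(drugs, ncol(A), adjacency = A, synthetic = TRUE)
}

# The standard toy bipartite graph: d1-c1, d1-c2, d2-c2, d2-c3.
toy_net <- function() {
  A <- matrix(0L, 2, 3, dimnames = list(c("d1", "d2"), c("1", "2", "3")))
  A["d1", 1] <- A["d1", 2] <- A["d2", 2] <- A["d2", 3] <- 1L
  make_net(A)
}

# Brute-force bipartite index scores by explicit set construction.
oracle_score <- function(A, i, j, method) {
  gamma_x <- which(A[i, ] == 1)
  adj_drugs <- which(A[, j] == 1)
  gamma_hat <- sort(unique(unlist(lapply(adj_drugs, function(w) which(A[w, ] == 1)))))
  cn <- length(intersect(gamma_x, gamma_hat))
  switch(method,
         CN = cn,
         JA = {
           u <- length(union(gamma_x, gamma_hat))
           if (u == 0) 0 else cn / u
         },
         PA = length(gamma_x) * length(adj_drugs))
}

oracle_score_matrix <- function(A, method) {
  S <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) S[i, j] <- oracle_score(A, i, j, method)
  }
  S
}

# Rank-based AUC with ties counted one half: mean over all positive-negative
# pairs of [score_pos > score_neg] + 0.5 [equal].
oracle_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Naive O(n^3) agglomerative clustering, average linkage (mean pairwise
# distance), distance ties broken by the lexicographically smallest pair of
# smallest member keys. Returns integer labels in input order.
oracle_agglom <- function(X, keys, k) {
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  while (length(clusters) > k) {
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        key <- paste(sort(c(min(keys[clusters[[a]]]), min(keys[clusters[[b]]]))),
                     collapse = "|")
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best_key) && key < best_key)) {
          best_d <- d
          best <- c(a, b)
          best_key <- key
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(X))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Partition equality up to relabeling.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# A tiny deterministic property table for fast embedding fits.
small_props <- function(P = 30, seed = 101) {
  generate_property_table(n_properties = P, seed = seed)
}

# A hand-made embedding whose amino-acid vectors are unit basis vectors:
# A = e1, C = e2, D = e3, E = e4, F = e5, all others zero.
basis_model <- function() {
  scores <- matrix(0, 20, 5, dimnames = list(amino_acid_codes(),
                                             paste0("PC", 1:5)))
  for (i in 1:5) scores[i, i] <- 1
  structure(list(scores = scores, n_components = 5,
                 eigenvalues = rep(1, 5), kept_columns = 1:5,
                 dropped_columns = integer(), amino_acids = rownames(scores)),
            class = "dca_embedding")
}

# A hand-made clustering with prescribed labels and centroids.
manual_clustering <- function(labels, k, d = 5) {
  keys <- names(labels)
  centroids <- matrix(seq_len(k * d) * 10, k, d)
  rownames(centroids) <- seq_len(k)
  structure(list(k = k, linkage = "average",
                 labels = tibble::tibble(canonical_key = keys,
                                         cluster = unname(labels)),
                 centroids = centroids, tree = NULL),
            class = "dca_clustering")
}

`%||%` <- rlang::`%||%`
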