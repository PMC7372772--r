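#' Build the bipartite drug-cluster association network
#'
#' Links drug d to cluster c (`a[d, c] = 1`) whenever some complex involving
#' d has a binding-site trimer assigned to c. Trimers seen at clustering
#' time keep their fitted label; unseen trimers are embedded and assigned to
#' the nearest centroid. Every edge carries evidence: the list of
#' (protein, complex, trimer) occurrences supporting it, which the
#' prediction-expansion step uses to name candidate trimers and proteins.
#'
#' Drugs are ordered by sorted ID and all k clusters are retained (degree 0
#' if empty), so rebuilding from the same inputs is bit-identical and the
#' n x m shape is stable across cross-validation folds.
#'
#' @param complexes A complex table (see [read_complex_table()]). Complexes
#'   whose site is shorter than 3 residues are skipped with a warning; the
#'   count is kept in the network.
#' @param clustering A fitted [cluster_trimers()] object.
#' @param model The [fit_embedding()] model used to vectorize unseen trimers.
#' @return An object of class `dca_network`: list with `drugs` (sorted IDs),
#'   `clusters` (1..k), `adjacency` (n x m binary matrix), `evidence`
#'   (tibble `drug_id`, `cluster`, `protein_id`, `complex_id`,
#'   `canonical_key`), `n_skipped`, `synthetic = FALSE`.
#' @seealso [generate_bipartite()] for evidence-free synthetic networks,
#'   [score_all()], [neighbor_sets()], [degree_summary()].
#' @export
build_network <- function(complexes, clustering, model) {
  stopifnot(inherits(clustering, "dca_clustering"), inherits(model, "dca_embedding"))
  trimers <- extract_trimers(complexes, on_short = "skip")
  n_skipped <- attr(trimers, "n_skipped") %||% 0L

  lookup <- setNames(clustering$labels$cluster, clustering$labels$canonical_key)
  keys <- unique(trimers$canonical_key)
  unseen <- setdiff(keys, names(lookup))
  if (length(unseen) > 0) {
    v <- vectorize_trimers(tibble(canonical_key = unseen), model)
    lookup <- c(lookup, setNames(assign_trimers(clustering, v), unseen))
  }
  trimers$cluster <- unname(lookup[trimers$canonical_key])

  evidence <- dplyr::distinct(
    trimers[, c("drug_id", "cluster", "protein_id", "complex_id", "canonical_key")])
  evidence <- dplyr::arrange(evidence, .data$drug_id, .data$cluster,
                             .data$protein_id, .data$complex_id, .data$canonical_key)

  drugs <- sort(unique(complexes$drug_id))
  new_dca_network(drugs, clustering$k, evidence = evidence, n_skipped = n_skipped)
}

# Shared constructor: adjacency either derived from evidence or given.
new_dca_network <- function(drugs, k, evidence = NULL, adjacency = NULL,
                            n_skipped = 0L, synthetic = FALSE) {
  clusters <- seq_len(k)
  if (is.null(adjacency)) {
    adjacency <- matrix(0L, length(drugs), k,
                        dimnames = list(drugs, as.character(clusters)))
    if (!is.null(evidence) && nrow(evidence) > 0) {
      adjacency[cbind(match(evidence$drug_id, drugs), evidence$cluster)] <- 1L
    }
  }
  structure(
    list(drugs = drugs, clusters = clusters, adjacency = adjacency,
         evidence = evidence, n_skipped = n_skipped, synthetic = synthetic),
    class = "dca_network")
}

#' Replace the adjacency of a network (edge removal for cross-validation)
#'
#' Returns a copy of `network` with the given edges removed from the
#' adjacency. Evidence is left untouched: this is the fold-level view used
#' to score held-out pairs without leaking them.
#'
#' @param network A `dca_network`.
#' @param edges Tibble with `drug_id` and `cluster` columns.
#' @return A `dca_network`.
#' @export
remove_edges <- function(network, edges) {
  stopifnot(inherits(network, "dca_network"))
  A <- network$adjacency
  A[cbind(match(edges$drug_id, network$drugs), edges$cluster)] <- 0L
  network$adjacency <- A
  network
}

#' Neighborhoods of a drug and a cluster in the bipartite graph
#'
#' In a bipartite graph a drug's neighbors are clusters and a cluster's
#' neighbors are drugs, so a drug and a cluster can never share a direct
#' common neighbor. The bipartite-adapted indices therefore compare the
#' drug's neighborhood Gamma(x) with the cluster's *two-hop* neighborhood
#' Gamma-hat(y): the set of clusters adjacent to any drug adjacent to y.
#' Whenever y has positive degree, y itself belongs to Gamma-hat(y).
#'
#' @param network A `dca_network`.
#' @param drug A drug ID present in the network.
#' @param cluster A cluster index present in the network.
#' @return A list with `gamma_drug` (integer cluster indices), `gamma_hat_cluster`
#'   (integer cluster indices, set semantics), `k_drug`, `k_cluster` (degrees).
#' @export
neighbor_sets <- function(network, drug, cluster) {
  stopifnot(inherits(network, "dca_network"))
  i <- match(drug, network$drugs)
  if (is.na(i)) abort(sprintf("unknown drug '%s'", drug))
  if (!cluster %in% network$clusters) abort(sprintf("unknown cluster %s", cluster))
  A <- network$adjacency
  gamma_x <- which(A[i, ] == 1L)
  adj_drugs <- which(A[, cluster] == 1L)
  gamma_hat <- sort(unique(unlist(lapply(adj_drugs, function(w) which(A[w, ] == 1L)))))
  list(gamma_drug = unname(gamma_x),
       gamma_hat_cluster = as.integer(gamma_hat),
       k_drug = length(gamma_x),
       k_cluster = length(adj_drugs))
}

#' Degree statistics of a drug-cluster network
#'
#' Exact degree histograms for both sides, edge density, and the two band
#' fractions used to describe network sparsity: the fraction of drugs whose
#' degree lies in `drug_band` (inclusive) and the fraction of clusters with
#' degree strictly below `cluster_below`. Also reports two-hop neighborhood
#' diagnostics for clusters under both set semantics (distinct clusters
#' reachable in two hops) and multiset semantics (path counts), since
#' published neighbor totals can follow either convention.
#'
#' @param network A `dca_network`.
#' @param drug_band Length-2 numeric, inclusive degree band for drugs.
#' @param cluster_below Scalar; clusters with degree `< cluster_below` are
#'   counted.
#' @return A list with `drug_degrees` and `cluster_degrees` (tibbles
#'   `degree`, `n`), `density`, `n_edges`, `frac_drugs_in_band`,
#'   `frac_clusters_below`, `two_hop_set_total`, `two_hop_multiset_total`.
#' @export
degree_summary <- function(network, drug_band = c(15, 30), cluster_below = 20) {
  stopifnot(inherits(network, "dca_network"))
  A <- network$adjacency
  kx <- rowSums(A)
  ky <- colSums(A)
  n_edges <- sum(A)
  cc <- crossprod(A)              # cluster x cluster shared-drug counts
  two_hop_set <- colSums(cc > 0)
  two_hop_multi <- as.vector(t(A) %*% kx)  # sum over adjacent drugs of their degrees
  list(
    drug_degrees = dplyr::count(tibble(degree = as.integer(kx)), .data$degree),
    cluster_degrees = dplyr::count(tibble(degree = as.integer(ky)), .data$degree),
    density = if (length(A) > 0) n_edges / length(A) else 0,
    n_edges = n_edges,
    frac_drugs_in_band = if (nrow(A) > 0) mean(kx >= drug_band[1] & kx <= drug_band[2]) else NA_real_,
    frac_clusters_below = if (ncol(A) > 0) mean(ky < cluster_below) else NA_real_,
    two_hop_set_total = sum(two_hop_set),
    two_hop_multiset_total = sum(two_hop_multi))
}

#' @export
print.dca_network <- function(x, ...) {
  cat(sprintf("<dca_network> %d drugs x %d clusters, %d edges (density %.3f)%s\n",
              length(x$drugs), length(x$clusters), sum(x$adjacency),
              sum(x$adjacency) / max(1, length(x$adjacency)),
              if (x$synthetic) " [synthetic, no evidence]" else ""))
  invisible(x)
}

#' @describeIn build_network Edges as a long tibble (`drug_id`, `cluster`).
#' @param x A `dca_network`.
#' @param ... Unused.
#' @method tidy dca_network
#' @export
tidy.dca_network <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  out <- tibble(drug_id = x$drugs[idx[, 1]], cluster = as.integer(idx[, 2]))
  dplyr::arrange(out, .data$drug_id, .data$cluster)
}

#' @describeIn build_network One-row summary (sizes, edges, density).
#' @method glance dca_network
#' @export
glance.dca_network <- function(x, ...) {
  tibble(n_drugs = length(x$drugs), n_clusters = length(x$clusters),
         n_edges = sum(x$adjacency),
         density = sum(x$adjacency) / max(1, length(x$adjacency)),
         n_skipped_complexes = x$n_skipped, synthetic = x$synthetic)
}

#' Serialize a network as edge list, dense adjacency and evidence TSVs
#'
#' @param network A `dca_network`.
#' @param edges_path,adjacency_path,evidence_path Output paths; pass `NULL`
#'   to skip a component (evidence is skipped automatically when absent).
#' @export
write_network <- function(network, edges_path = NULL, adjacency_path = NULL,
                          evidence_path = NULL) {
  stopifnot(inherits(network, "dca_network"))
  if (!is.null(edges_path)) write_tsv_12(tidy(network), edges_path)
  if (!is.null(adjacency_path)) {
    adj <- dplyr::bind_cols(tibble(drug_id = network$drugs),
                            as_tibble(network$adjacency, .name_repair = "minimal"))
    names(adj) <- c("drug_id", paste0("c", network$clusters))
    write_tsv_12(adj, adjacency_path)
  }
  if (!is.null(evidence_path) && !is.null(network$evidence)) {
    write_tsv_12(network$evidence, evidence_path)
  }
  invisible(network)
}
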