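#' Bipartite link-prediction indices for one drug-cluster pair
#'
#' The three indices adapted to the bipartite drug-cluster graph score a
#' pair (x, y) from the drug neighborhood Gamma(x) and the cluster two-hop
#' neighborhood Gamma-hat(y) (see [neighbor_sets()]):
#' \describe{
#'   \item{CN}{`|Gamma(x) intersect Gamma-hat(y)|` -- common neighbours.}
#'   \item{JA}{`|Gamma(x) intersect Gamma-hat(y)| / |Gamma(x) union Gamma-hat(y)|`
#'     -- Jaccard; 0 when both sets are empty.}
#'   \item{PA}{`k_x * k_y` -- preferential attachment on the raw degrees.}
#' }
#' Gamma-hat(y) uses set semantics (each cluster counted once regardless of
#' how many drugs connect it to y); a multiset variant is available in
#' [score_all()] for sensitivity analysis.
#'
#' @param network A `dca_network`.
#' @param drug Drug ID.
#' @param cluster Cluster index.
#' @return A single number (non-negative integer for CN and PA, a value in
#'   `[0, 1]` for JA).
#' @examples
#' net <- generate_bipartite(6, 8, density = 0.4, seed = 7)
#' score_cn(net, net$drugs[1], 3)
#' @export
score_cn <- function(network, drug, cluster) {
  ns <- neighbor_sets(network, drug, cluster)
  length(intersect(ns$gamma_drug, ns$gamma_hat_cluster))
}

#' @rdname score_cn
#' @export
score_jaccard <- function(network, drug, cluster) {
  ns <- neighbor_sets(network, drug, cluster)
  u <- length(union(ns$gamma_drug, ns$gamma_hat_cluster))
  if (u == 0) return(0)
  length(intersect(ns$gamma_drug, ns$gamma_hat_cluster)) / u
}

#' @rdname score_cn
#' @export
score_pa <- function(network, drug, cluster) {
  ns <- neighbor_sets(network, drug, cluster)
  ns$k_drug * ns$k_cluster
}

#' Score every drug-cluster pair of a network
#'
#' Computes the chosen index for all n x m pairs, known edges included
#' (they are flagged by the `known_mask` so evaluation can exclude them).
#' Entirely deterministic.
#'
#' @param network A `dca_network`.
#' @param method `"CN"`, `"JA"` or `"PA"`.
#' @param gamma_hat `"set"` (default; distinct two-hop clusters) or
#'   `"multiset"` (two-hop path counts weight the intersection) -- the
#'   latter is a sensitivity-analysis variant for CN only.
#' @return An object of class `dca_scores`: list with `method`, `scores`
#'   (n x m numeric matrix, dimnames drugs x clusters) and `known_mask`
#'   (copy of the adjacency).
#' @seealso [threshold_scores()], [tidy.dca_scores()]
#' @export
score_all <- function(network, method = c("CN", "JA", "PA"),
                      gamma_hat = c("set", "multiset")) {
  method <- match.arg(method)
  gamma_hat <- match.arg(gamma_hat)
  stopifnot(inherits(network, "dca_network"))
  A <- network$adjacency
  storage.mode(A) <- "double"
  kx <- rowSums(A)
  ky <- colSums(A)
  S <- if (method == "PA") {
    outer(kx, ky)
  } else {
    cc <- crossprod(A)                       # shared-drug counts between clusters
    hat <- if (gamma_hat == "multiset") cc else (cc > 0) * 1
    CN <- A %*% hat                          # |Gamma(x) ∩ Gamma-hat(y)| (weighted if multiset)
    if (method == "CN") {
      CN
    } else {
      ghat_size <- colSums(hat > 0)
      un <- outer(kx, rep(1, ncol(A))) + outer(rep(1, nrow(A)), ghat_size) - CN
      ifelse(un == 0, 0, CN / un)
    }
  }
  dimnames(S) <- dimnames(network$adjacency)
  structure(list(method = method, gamma_hat = gamma_hat, scores = S,
                 known_mask = network$adjacency),
            class = "dca_scores")
}

#' @export
print.dca_scores <- function(x, ...) {
  cat(sprintf("<dca_scores> %s index, %d x %d pairs, %d non-zero\n",
              x$method, nrow(x$scores), ncol(x$scores), sum(x$scores > 0)))
  invisible(x)
}

#' @describeIn score_all Long tibble `drug_id`, `cluster`, `score`, `known`.
#' @param x A `dca_scores`.
#' @param ... Unused.
#' @method tidy dca_scores
#' @export
tidy.dca_scores <- function(x, ...) {
  tibble(drug_id = rep(rownames(x$scores), times = ncol(x$scores)),
         cluster = rep(as.integer(colnames(x$scores)), each = nrow(x$scores)),
         score = as.vector(x$scores),
         known = as.vector(x$known_mask) == 1) |>
    dplyr::arrange(.data$drug_id, .data$cluster)
}

#' Threshold a score matrix into significant and important associations
#'
#' An association is *significant* when its score exceeds
#' `significant_cutoff` (strictly). Among the significant ones, the
#' *important* set is either everything above the absolute
#' `important_cutoff` when given, or the top `important_fraction` by score
#' (count = `ceiling(fraction * n_significant)`); boundary ties are all
#' included so the rule is deterministic.
#'
#' @param scores A `dca_scores` object.
#' @param significant_cutoff Absolute cutoff, or `"quantile"` semantics via
#'   [significance_cutoff_se()] upstream; the pipeline's default derives it
#'   from fold-resampling score standard errors.
#' @param important_fraction Fraction of the significant set, in (0, 1].
#' @param important_cutoff Optional absolute cutoff taking precedence over
#'   the fraction.
#' @return A list with `significant` and `important` (tibbles `drug_id`,
#'   `cluster`, `score`, `known`, sorted by decreasing score) and `counts`
#'   (`n_nonzero`, `n_significant`, `n_important`).
#' @examples
#' net <- generate_bipartite(8, 8, density = 0.3, seed = 2)
#' th <- threshold_scores(score_all(net, "PA"), significant_cutoff = 4)
#' th$counts
#' @export
threshold_scores <- function(scores, significant_cutoff,
                             important_fraction = 0.2, important_cutoff = NULL) {
  stopifnot(inherits(scores, "dca_scores"), is.numeric(significant_cutoff))
  long <- tidy(scores)
  long <- dplyr::arrange(long, dplyr::desc(.data$score), .data$drug_id, .data$cluster)
  sig <- long[long$score > significant_cutoff, , drop = FALSE]
  imp <- if (!is.null(important_cutoff)) {
    sig[sig$score > important_cutoff, , drop = FALSE]
  } else if (nrow(sig) == 0) {
    sig
  } else {
    stopifnot(important_fraction > 0, important_fraction <= 1)
    n_imp <- ceiling(important_fraction * nrow(sig))
    boundary <- sig$score[n_imp]
    sig[sig$score >= boundary, , drop = FALSE]   # boundary ties included
  }
  list(significant = sig, important = imp,
       counts = list(n_nonzero = sum(long$score > 0),
                     n_significant = nrow(sig),
                     n_important = nrow(imp)))
}

#' Fold-resampling standard-error cutoff for significance
#'
#' An automatic choice of the significance cutoff: the network's edges are
#' split into `n_folds` folds; each fold's edges are removed in turn and all
#' pairs rescored, giving `n_folds` training-network score matrices. The
#' cutoff is the mean over pairs of the per-pair standard deviation of those
#' scores -- an estimate of how much a score moves under resampling of the
#' observed edges.
#'
#' @param network A `dca_network`.
#' @param method Index passed to [score_all()].
#' @param n_folds Number of folds (default 10).
#' @param seed Optional integer seed for the fold shuffle.
#' @return A single non-negative number.
#' @export
significance_cutoff_se <- function(network, method = "CN", n_folds = 10, seed = NULL) {
  edges <- tidy(network)
  folds <- make_folds(edges, n_folds = n_folds, seed = seed)
  mats <- lapply(folds, function(f) {
    score_all(remove_edges(network, f$test), method)$scores
  })
  arr <- simplify2array(mats)
  per_pair_sd <- apply(arr, c(1, 2), sd)
  mean(per_pair_sd)
}

#' Expand significant drug-cluster associations to trimer and protein candidates
#'
#' For each significant pair (drug d, cluster c), every member trimer of c
#' observed at any binding site yields a drug-trimer candidate (d, t), and
#' every protein whose site carries such a trimer yields a drug-protein
#' candidate (d, p). The novelty flag marks pairs not already supported by a
#' known complex: a drug-protein pair is known when some complex pairs them,
#' and a drug-trimer pair is known when the drug's own sites contain the
#' trimer.
#'
#' Requires a network built with evidence ([build_network()]); synthetic
#' evidence-free networks are rejected.
#'
#' @param network A `dca_network` with evidence.
#' @param significant A tibble with `drug_id` and `cluster` columns (e.g.
#'   `threshold_scores()$significant`).
#' @return A list with `drug_trimer` (tibble `drug_id`, `cluster`,
#'   `canonical_key`, `novel`) and `drug_protein` (tibble `drug_id`,
#'   `cluster`, `protein_id`, `novel`).
#' @export
expand_predictions <- function(network, significant) {
  stopifnot(inherits(network, "dca_network"))
  if (is.null(network$evidence)) {
    abort("network carries no evidence (synthetic bipartite networks cannot be expanded)")
  }
  ev <- network$evidence
  sig <- dplyr::distinct(as_tibble(significant)[c("drug_id", "cluster")])
  if (nrow(sig) == 0) {
    return(list(drug_trimer = tibble(drug_id = character(), cluster = integer(),
                                     canonical_key = character(), novel = logical()),
                drug_protein = tibble(drug_id = character(), cluster = integer(),
                                      protein_id = character(), novel = logical())))
  }
  members <- dplyr::distinct(ev[c("cluster", "canonical_key", "protein_id")])
  dt <- dplyr::distinct(
    dplyr::inner_join(sig, members[c("cluster", "canonical_key")],
                      by = "cluster", relationship = "many-to-many"))
  dp <- dplyr::distinct(
    dplyr::inner_join(sig, members[c("cluster", "protein_id")],
                      by = "cluster", relationship = "many-to-many"))
  known_dt <- dplyr::distinct(ev[c("drug_id", "canonical_key")])
  known_dp <- dplyr::distinct(ev[c("drug_id", "protein_id")])
  dt$novel <- !paste(dt$drug_id, dt$canonical_key) %in%
    paste(known_dt$drug_id, known_dt$canonical_key)
  dp$novel <- !paste(dp$drug_id, dp$protein_id) %in%
    paste(known_dp$drug_id, known_dp$protein_id)
  list(drug_trimer = dplyr::arrange(dt, .data$drug_id, .data$cluster, .data$canonical_key),
       drug_protein = dplyr::arrange(dp, .data$drug_id, .data$cluster, .data$protein_id))
}
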