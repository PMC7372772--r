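#' Agglomeratively cluster trimer vectors
#'
#' Hierarchically clusters the distinct trimer vectors (Euclidean distance,
#' average linkage by default) and cuts the tree into exactly `k` clusters.
#' In the drug-cluster association model `k` is the number of distinct drugs
#' in the dataset, so each cluster can be read as a physicochemical "group"
#' that a drug class binds.
#'
#' Trimers are sorted by canonical key before clustering, so the partition
#' is independent of input order. Cluster indices are 1-based and assigned
#' by decreasing cluster size, with ties broken by the smallest member key.
#'
#' @param vectors A tibble from [vectorize_trimers()]: `canonical_key` plus
#'   numeric component columns.
#' @param k Number of clusters (1 <= k <= number of trimers).
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"`. Average linkage is the default because single linkage chains
#'   badly in a continuous 5-d space while the model's reading of clusters
#'   as compact chemical groups wants tight clusters.
#' @return An object of class `dca_clustering`: list with `k`, `linkage`,
#'   `labels` (tibble `canonical_key`, `cluster`), `centroids` (k x d
#'   matrix, row i = mean vector of cluster i) and `tree` (the `hclust`
#'   merge record, for audit and for nested cuts).
#' @examples
#' props <- generate_property_table(seed = 1)
#' emb <- fit_embedding(props)
#' v <- vectorize_trimers(trimer_windows("NGMGKRDEW"), emb)
#' cl <- cluster_trimers(v, k = 3)
#' tidy(cl)
#' @export
cluster_trimers <- function(vectors, k, linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  vectors <- dplyr::arrange(as_tibble(vectors), .data$canonical_key)
  X <- as.matrix(vectors[setdiff(names(vectors), "canonical_key")])
  rownames(X) <- vectors$canonical_key
  n <- nrow(X)
  if (n < k) {
    abort(sprintf("cannot form %d clusters from %d trimers", k, n))
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(dist(X), method = method)
  raw_labels <- if (k == n) seq_len(n) else cutree(tree, k = k)
  labels <- relabel_clusters(raw_labels, rownames(X), k)
  centroids <- t(vapply(seq_len(k),
                        function(i) colMeans(X[labels == i, , drop = FALSE]),
                        numeric(ncol(X))))
  rownames(centroids) <- seq_len(k)
  structure(
    list(k = k, linkage = linkage,
         labels = tibble(canonical_key = rownames(X), cluster = labels),
         centroids = centroids, tree = tree),
    class = "dca_clustering")
}

# Reindex raw cluster labels: 1 = largest cluster, ties by smallest member key.
relabel_clusters <- function(raw, keys, k) {
  sizes <- tabulate(raw, nbins = k)
  min_key <- vapply(seq_len(k), function(i) min(keys[raw == i]), "")
  ord <- order(-sizes, min_key)
  new_of_raw <- integer(k)
  new_of_raw[ord] <- seq_len(k)
  new_of_raw[raw]
}

#' Assign vectors to the nearest cluster centroid
#'
#' Used for trimers not seen at fit time (e.g. an independent test set of
#' complexes): each vector is assigned to the cluster whose centroid is
#' nearest in Euclidean distance, ties going to the lowest cluster index.
#'
#' @param clustering A fitted [cluster_trimers()] object.
#' @param vectors A numeric vector (one trimer), a matrix, or a tibble from
#'   [vectorize_trimers()].
#' @return An integer vector of cluster indices.
#' @export
assign_trimers <- function(clustering, vectors) {
  stopifnot(inherits(clustering, "dca_clustering"))
  if (is.data.frame(vectors)) {
    vectors <- as.matrix(vectors[setdiff(names(vectors), "canonical_key")])
  }
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  C <- clustering$centroids
  # squared distances via the expansion ||v||^2 - 2 v.c + ||c||^2
  d2 <- outer(rowSums(vectors^2), rep(1, nrow(C))) -
    2 * vectors %*% t(C) + outer(rep(1, nrow(vectors)), rowSums(C^2))
  apply(round(d2, 12), 1, which.min)
}

#' @export
print.dca_clustering <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat(sprintf("<dca_clustering> %d trimers in %d clusters (%s linkage); sizes %d-%d\n",
              nrow(x$labels), x$k, x$linkage, min(sizes), max(sizes)))
  invisible(x)
}

#' @describeIn cluster_trimers Per-trimer labels as a tibble.
#' @param x A `dca_clustering`.
#' @param ... Unused.
#' @method tidy dca_clustering
#' @export
tidy.dca_clustering <- function(x, ...) x$labels

#' @describeIn cluster_trimers One-row summary (k, linkage, size spread).
#' @method glance dca_clustering
#' @export
glance.dca_clustering <- function(x, ...) {
  sizes <- tabulate(x$labels$cluster, nbins = x$k)
  tibble(k = x$k, linkage = x$linkage, n_trimers = nrow(x$labels),
         min_size = min(sizes), max_size = max(sizes),
         mean_size = mean(sizes))
}

#' Serialize / restore a clustering
#'
#' Labels and centroids are written as TSV (the merge record is not
#' serialized; restored objects support assignment but not re-cutting).
#'
#' @param clustering A `dca_clustering`.
#' @param labels_path,centroids_path File paths.
#' @export
write_clustering <- function(clustering, labels_path, centroids_path) {
  write_tsv_12(clustering$labels, labels_path)
  cent <- dplyr::bind_cols(tibble(cluster = seq_len(clustering$k)),
                           as_tibble(clustering$centroids, .name_repair = "minimal"))
  names(cent) <- c("cluster", paste0("V", seq_len(ncol(clustering$centroids))))
  write_tsv_12(cent, centroids_path)
  invisible(labels_path)
}

#' @rdname write_clustering
#' @param linkage Linkage recorded with the restored object.
#' @export
read_clustering <- function(labels_path, centroids_path, linkage = "average") {
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
  cent <- readr::read_tsv(centroids_path, show_col_types = FALSE, progress = FALSE)
  centroids <- as.matrix(cent[-1])
  rownames(centroids) <- cent$cluster
  structure(
    list(k = nrow(centroids), linkage = linkage,
         labels = tibble(canonical_key = labels$canonical_key,
                         cluster = as.integer(labels$cluster)),
         centroids = centroids, tree = NULL),
    class = "dca_clustering")
}
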