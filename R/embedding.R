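#' Fit a physicochemical PCA embedding of the 20 amino acids
#'
#' Reduces the 20 x P property matrix to a low-dimensional vector per amino
#' acid. Property columns are standardized (zero mean, unit variance over the
#' 20 amino acids) -- the descriptors mix units, so unstandardized PCA would
#' be dominated by large-unit properties -- then the covariance of the
#' standardized columns is eigen-decomposed and the top `n_components`
#' eigenpairs retained. Amino-acid coordinates are the projections of the
#' standardized rows onto the unit eigenvectors (the score convention), so
#' the variance of component i over the 20 amino acids equals the i-th
#' eigenvalue.
#'
#' Zero-variance columns are dropped before standardization (their indices
#' are recorded in the model). Each axis's sign is fixed so that its
#' largest-magnitude loading is positive, making the embedding reproducible
#' across linear-algebra backends.
#'
#' @param tbl An amino-acid property table (see [read_property_table()]).
#' @param n_components Number of components to keep; defaults to 5, and may
#'   not exceed the rank of the standardized matrix (at most 19).
#' @return An object of class `dca_embedding`: a list with `column_means`,
#'   `column_sds`, `kept_columns`, `eigenvalues` (all of them, descending),
#'   `axes` (P_kept x n_components, orthonormal columns), `scores`
#'   (20 x n_components matrix of amino-acid coordinates) and
#'   `n_components`.
#' @examples
#' props <- generate_property_table(seed = 1)
#' emb <- fit_embedding(props)
#' glance(emb)
#' embed_amino_acid(emb, "W")
#' @export
fit_embedding <- function(tbl, n_components = 5) {
  tbl <- validate_property_table(tbl)
  X <- as.matrix(tbl[-1])
  rownames(X) <- tbl$amino_acid
  storage.mode(X) <- "double"

  sds <- apply(X, 2, sd)
  kept <- which(sds > 1e-12)
  if (length(kept) < 5) {
    abort("fewer than 5 non-degenerate property columns after dropping zero-variance columns")
  }
  Xk <- X[, kept, drop = FALSE]
  mu <- colMeans(Xk)
  sdk <- sds[kept]
  Z <- sweep(sweep(Xk, 2, mu, "-"), 2, sdk, "/")

  eig <- eigen(cov(Z), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  rank <- sum(vals > max(vals) * 1e-10)
  if (n_components > min(rank, nrow(X) - 1L)) {
    abort(sprintf("n_components = %d exceeds the available rank (%d)",
                  n_components, min(rank, nrow(X) - 1L)))
  }
  axes <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: the largest-magnitude loading of each axis is positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(Xk)
  colnames(axes) <- paste0("PC", seq_len(n_components))
  scores <- Z %*% axes

  structure(
    list(column_means = mu, column_sds = sdk, kept_columns = kept,
         dropped_columns = setdiff(seq_along(sds), kept),
         eigenvalues = vals, axes = axes, scores = scores,
         n_components = n_components,
         amino_acids = tbl$amino_acid),
    class = "dca_embedding")
}

#' Embed one amino acid
#'
#' Returns the fitted low-dimensional coordinates of a standard amino acid:
#' the projection of its standardized property row onto the retained
#' principal axes. A pure function of the property row, so amino acids with
#' identical rows embed identically.
#'
#' @param model A fitted [fit_embedding()] model.
#' @param code One-letter amino-acid code.
#' @return A named numeric vector of length `n_components`.
#' @export
embed_amino_acid <- function(model, code) {
  stopifnot(inherits(model, "dca_embedding"))
  check_residues(code, "amino-acid")
  drop(model$scores[code, ])
}

#' All 20 amino-acid embeddings as a tibble
#'
#' @param model A fitted [fit_embedding()] model.
#' @return A tibble with `amino_acid` and one column per component.
#' @export
aa_vectors <- function(model) {
  stopifnot(inherits(model, "dca_embedding"))
  dplyr::bind_cols(tibble(amino_acid = rownames(model$scores)),
                   as_tibble(model$scores))
}

#' @export
print.dca_embedding <- function(x, ...) {
  cat(sprintf("<dca_embedding> %d components over %d properties (%d dropped)\n",
              x$n_components, length(x$kept_columns), length(x$dropped_columns)))
  ev <- x$eigenvalues[seq_len(x$n_components)]
  cat(sprintf("  eigenvalues: %s (%.1f%% of total variance)\n",
              paste(sprintf("%.3g", ev), collapse = ", "),
              100 * sum(ev) / sum(x$eigenvalues)))
  invisible(x)
}

#' @describeIn fit_embedding One row per retained component: eigenvalue and
#'   variance fractions.
#' @param x,object A `dca_embedding`.
#' @param ... Unused.
#' @method tidy dca_embedding
#' @export
tidy.dca_embedding <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(x$n_components)]
  tibble(component = paste0("PC", seq_along(ev)),
         eigenvalue = ev,
         prop_variance = ev / sum(x$eigenvalues),
         cum_variance = cumsum(ev) / sum(x$eigenvalues))
}

#' @describeIn fit_embedding One-row summary of the fit.
#' @method glance dca_embedding
#' @export
glance.dca_embedding <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(x$n_components)]
  tibble(n_components = x$n_components,
         n_properties = length(x$kept_columns),
         n_dropped = length(x$dropped_columns),
         total_variance = sum(x$eigenvalues),
         explained_variance = sum(ev) / sum(x$eigenvalues))
}

#' Serialize / restore an embedding model
#'
#' The model (means, sds, kept columns, eigenvalues, axes, scores) is
#' written as a single JSON document so it can be reused by the pipeline and
#' the command-line driver; numbers round-trip losslessly.
#'
#' @param model A `dca_embedding`.
#' @param path File path.
#' @return `read_embedding()` returns the restored `dca_embedding`.
#' @export
write_embedding <- function(model, path) {
  stopifnot(inherits(model, "dca_embedding"))
  payload <- list(
    column_means = as.list(model$column_means),
    column_sds = as.list(model$column_sds),
    kept_columns = model$kept_columns,
    dropped_columns = model$dropped_columns,
    eigenvalues = model$eigenvalues,
    axes = apply(model$axes, 2, identity, simplify = FALSE),
    axis_rows = rownames(model$axes),
    scores = apply(model$scores, 2, identity, simplify = FALSE),
    amino_acids = model$amino_acids,
    n_components = model$n_components)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- do.call(cbind, p$axes)
  rownames(axes) <- p$axis_rows
  scores <- do.call(cbind, p$scores)
  rownames(scores) <- p$amino_acids
  structure(
    list(column_means = unlist(p$column_means), column_sds = unlist(p$column_sds),
         kept_columns = p$kept_columns, dropped_columns = p$dropped_columns,
         eigenvalues = p$eigenvalues, axes = axes, scores = scores,
         n_components = p$n_components, amino_acids = p$amino_acids),
    class = "dca_embedding")
}
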