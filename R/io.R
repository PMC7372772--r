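#' Write and read score matrices
#'
#' The dense form is a TSV with one row per drug and one score column per
#' cluster (`c1`, `c2`, ...), written with 12 significant digits so that a
#' write/read round-trip reproduces the matrix to that precision. The long
#' form ([write_edge_list()]) has one row per pair: drug, cluster, score and
#' the known flag, optionally annotated with significant/important flags.
#'
#' @param scores A `dca_scores` object.
#' @param path Output path.
#' @export
write_score_matrix <- function(scores, path) {
  stopifnot(inherits(scores, "dca_scores"))
  tbl <- dplyr::bind_cols(tibble(drug_id = rownames(scores$scores)),
                          as_tibble(scores$scores, .name_repair = "minimal"))
  names(tbl) <- c("drug_id", paste0("c", colnames(scores$scores)))
  write_tsv_12(tbl, path)
  invisible(path)
}

#' @rdname write_score_matrix
#' @param method Method label attached to the restored object.
#' @return `read_score_matrix()` returns a `dca_scores` with an all-zero
#'   known mask (the adjacency is not part of the dense file).
#' @export
read_score_matrix <- function(path, method = "CN") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  S <- as.matrix(tbl[-1])
  dimnames(S) <- list(tbl$drug_id, sub("^c", "", colnames(S)))
  structure(list(method = method, gamma_hat = "set", scores = S,
                 known_mask = matrix(0L, nrow(S), ncol(S), dimnames = dimnames(S))),
            class = "dca_scores")
}

#' @rdname write_score_matrix
#' @param x A `dca_scores` object or a `dca_network` (edges only).
#' @param thresholds Optional result of [threshold_scores()]; adds
#'   `significant` and `important` flag columns.
#' @export
write_edge_list <- function(x, path, thresholds = NULL) {
  long <- tidy(x)
  if (!is.null(thresholds)) {
    key <- function(d) paste(d$drug_id, d$cluster)
    long$significant <- key(long) %in% key(thresholds$significant)
    long$important <- key(long) %in% key(thresholds$important)
  }
  write_tsv_12(long, path)
  invisible(path)
}

#' Write and read an evaluation report
#'
#' The report is one structured-text (JSON) document holding all metrics,
#' curves and the configuration echo; numbers are written at full precision
#' so the document round-trips losslessly.
#'
#' @param report A named list (e.g. the report assembled by
#'   [run_pipeline()]), or a `dca_cv` object (serialized as per-fold
#'   metrics, means and config).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "dca_cv")) {
    report <- list(method = report$method, per_fold = report$metrics,
                   mean = as.list(glance(report)), config = report$config)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the report as a list (data frames
#'   restored as tibbles).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rapply(rep, as_tibble, classes = "data.frame", how = "replace")
}
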