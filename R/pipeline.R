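#' Pipeline configuration
#'
#' Collects every knob of the end-to-end drug-cluster association pipeline.
#' Defaults follow the reference workflow: `k = "auto"` (one cluster per
#' distinct drug), 5 embedding components, average linkage, the CN index,
#' 10-fold cross-validation with 1:1 negative sampling, and 100 benchmark
#' repetitions.
#'
#' @param property_table Path to a property table, or the table itself.
#' @param complex_table Path to a complex table, or the table itself.
#' @param out_dir Output directory (created if missing).
#' @param k Cluster count, or `"auto"` for the number of distinct drugs.
#' @param linkage Linkage for [cluster_trimers()].
#' @param n_components Embedding dimensionality.
#' @param method Link-prediction index, `"CN"`, `"JA"` or `"PA"`.
#' @param sig_cutoff Significance cutoff: a number, or `"se"` to derive it
#'   from fold-resampling score standard errors
#'   ([significance_cutoff_se()]).
#' @param top_frac Fraction of significant associations flagged important.
#' @param n_folds,neg_ratio,benchmark_reps Evaluation settings.
#' @param seed Integer seed covering all randomness.
#' @return A list of class `dca_config`.
#' @export
pipeline_config <- function(property_table, complex_table, out_dir,
                            k = "auto", linkage = "average", n_components = 5,
                            method = "CN", sig_cutoff = "se", top_frac = 0.2,
                            n_folds = 10, neg_ratio = 1, benchmark_reps = 100,
                            seed = 1) {
  structure(as.list(environment()), class = "dca_config")
}

#' Run the full drug-cluster association pipeline
#'
#' Executes, in order: input reading and validation, PCA embedding of the
#' amino acids, trimer extraction and vectorization, hierarchical
#' clustering, bipartite network construction, link-prediction scoring with
#' significance thresholding and prediction expansion, and cross-validated
#' evaluation with the benchmark baseline. Every stage's output is
#' serialized under `out_dir`, and `manifest.yaml` records the
#' configuration, seed and per-stage record counts -- enough to re-run the
#' pipeline identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage objects (`embedding`,
#'   `trimers`, `clustering`, `network`, `scores`, `thresholds`,
#'   `expanded`, `cv`, `baseline`) and `manifest`.
#' @examples
#' \donttest{
#' synth <- generate_complexes(synthetic_spec(n_drugs = 12, n_complexes = 15,
#'                                            n_proteins = 8), seed = 1)
#' props <- generate_property_table(n_properties = 40, seed = 2)
#' cfg <- pipeline_config(props, synth$complexes, tempfile("dca"),
#'                        n_folds = 5, benchmark_reps = 5, seed = 9)
#' res <- run_pipeline(cfg)
#' res$manifest$counts
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dca_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  counts <- list()

  props <- stage("io", {
    p <- config$property_table
    if (is.character(p)) read_property_table(p) else validate_property_table(p)
  })
  complexes <- stage("io", {
    p <- config$complex_table
    if (is.character(p)) read_complex_table(p) else validate_complex_table(p)
  })
  counts$n_complexes <- nrow(complexes)
  counts$n_properties <- ncol(props) - 1L

  model <- stage("embedding", fit_embedding(props, config$n_components))
  write_embedding(model, out("embedding.json"))

  trimers <- stage("trimers", extract_trimers(complexes, on_short = "skip"))
  counts$n_trimer_occurrences <- nrow(trimers)
  counts$n_unique_trimers <- dplyr::n_distinct(trimers$canonical_key)
  write_tsv_12(trimers, out("trimers.tsv"))

  vectors <- stage("trimers", vectorize_trimers(trimers, model))
  k <- if (identical(config$k, "auto")) dplyr::n_distinct(complexes$drug_id) else config$k
  clustering <- stage("clustering", cluster_trimers(vectors, k = k,
                                                    linkage = config$linkage))
  counts$k <- clustering$k
  write_clustering(clustering, out("cluster_labels.tsv"), out("cluster_centroids.tsv"))

  network <- stage("network", build_network(complexes, clustering, model))
  counts$n_drugs <- length(network$drugs)
  counts$n_edges <- sum(network$adjacency)
  write_network(network, out("edges.tsv"), out("adjacency.tsv"), out("evidence.tsv"))

  scores <- stage("link_prediction", score_all(network, config$method))
  write_score_matrix(scores, out("score_matrix.tsv"))
  write_edge_list(scores, out("score_edges.tsv"))
  cutoff <- stage("link_prediction", {
    if (identical(config$sig_cutoff, "se")) {
      significance_cutoff_se(network, config$method, config$n_folds,
                             seed = config$seed)
    } else config$sig_cutoff
  })
  thr <- stage("link_prediction",
               threshold_scores(scores, cutoff, important_fraction = config$top_frac))
  counts$sig_cutoff <- cutoff
  counts$n_significant <- thr$counts$n_significant
  counts$n_important <- thr$counts$n_important
  write_tsv_12(thr$significant, out("significant.tsv"))
  write_tsv_12(thr$important, out("important.tsv"))
  expanded <- stage("link_prediction", expand_predictions(network, thr$significant))
  counts$n_drug_trimer <- nrow(expanded$drug_trimer)
  counts$n_drug_protein <- nrow(expanded$drug_protein)
  write_tsv_12(expanded$drug_trimer, out("predicted_drug_trimer.tsv"))
  write_tsv_12(expanded$drug_protein, out("predicted_drug_protein.tsv"))

  cv <- stage("evaluation", run_cv(network, config$method, n_folds = config$n_folds,
                                   negatives_per_positive = config$neg_ratio,
                                   seed = config$seed))
  baseline <- stage("evaluation", {
    if (config$benchmark_reps > 0) {
      benchmark_baseline(network, config$method, repetitions = config$benchmark_reps,
                         n_folds = config$n_folds,
                         negatives_per_positive = config$neg_ratio,
                         seed = config$seed + 1L)
    } else NULL
  })
  report <- c(
    list(method = config$method,
         per_fold = cv$metrics,
         mean = as.list(glance(cv))),
    if (!is.null(baseline)) list(
      baseline_auc = baseline$auc, baseline_se = baseline$se,
      adjusted_auc = glance(cv)$auc - baseline$auc),
    list(config = config[setdiff(names(config), c("property_table", "complex_table"))]))
  write_report(report, out("evaluation_report.json"))
  purrr::iwalk(cv$curves, function(cur, f) {
    write_tsv_12(cur$roc, out(sprintf("roc_fold%02d.tsv", f)))
    write_tsv_12(cur$pr, out(sprintf("pr_fold%02d.tsv", f)))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcanet")),
    seed = config$seed,
    config = config[setdiff(names(config), c("property_table", "complex_table"))],
    counts = counts)
  yaml::write_yaml(manifest, out("manifest.yaml"))

  invisible(list(embedding = model, trimers = trimers, clustering = clustering,
                 network = network, scores = scores, thresholds = thr,
                 expanded = expanded, cv = cv, baseline = baseline,
                 manifest = manifest))
}
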