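#' Plot cross-validation ROC and PR curves
#'
#' One line per fold, with the chance diagonal for the ROC panel. Returns a
#' ggplot; choose the panel with `type`.
#'
#' @param object A `dca_cv` report.
#' @param type `"roc"` (default) or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dca_cv
#' @export
autoplot.dca_cv <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  curves <- dplyr::bind_rows(
    purrr::imap(object$curves, function(cur, f) {
      dplyr::mutate(cur[[type]], fold = factor(f))
    }))
  if (type == "roc") {
    ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$fold)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("%s: ROC by fold (mean AUC %.3f)",
                                    object$method, glance(object)$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(curves, ggplot2::aes(.data$recall, .data$precision,
                                         colour = .data$fold)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("%s: PR by fold (mean AUPR %.3f)",
                                    object$method, glance(object)$aupr)) +
      ggplot2::theme_minimal()
  }
}

#' Plot the degree distributions of a drug-cluster network
#'
#' Side-by-side histograms of drug and cluster degrees.
#'
#' @param object A `dca_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dca_network
#' @export
autoplot.dca_network <- function(object, ...) {
  ds <- degree_summary(object)
  both <- dplyr::bind_rows(
    dplyr::mutate(ds$drug_degrees, side = "drugs"),
    dplyr::mutate(ds$cluster_degrees, side = "clusters"))
  ggplot2::ggplot(both, ggplot2::aes(.data$degree, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~side, scales = "free") +
    ggplot2::labs(x = "Degree", y = "Count",
                  title = sprintf("Degree distributions (density %.3f)", ds$density)) +
    ggplot2::theme_minimal()
}

#' Plot a score matrix as a heatmap
#'
#' Tiles drugs by clusters coloured by score; optional thresholds outline
#' the significant set.
#'
#' @param object A `dca_scores` object.
#' @param thresholds Optional [threshold_scores()] result; significant
#'   pairs are overplotted as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dca_scores
#' @export
autoplot.dca_scores <- function(object, thresholds = NULL, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$cluster, .data$drug_id,
                                          fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Cluster", y = "Drug",
                  title = sprintf("%s score matrix", object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(thresholds) && nrow(thresholds$significant) > 0) {
    p <- p + ggplot2::geom_point(data = thresholds$significant,
                                 ggplot2::aes(.data$cluster, .data$drug_id),
                                 inherit.aes = FALSE, size = 0.3, colour = "red")
  }
  p
}
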