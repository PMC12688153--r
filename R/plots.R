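# ggplot2 visualisations of the main result types.

#' Plot titration curves
#'
#' Mean ionisation against pH for every site in a titration run.
#'
#' @param object A `titration_curves` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_curves <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$ph, y = .data$ionisation,
                 colour = .data$site_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "pH", y = "mean ionisation", colour = "site") +
    ggplot2::theme_minimal()
}

#' Plot a ROC scan
#'
#' One point per threshold cell, optionally grouped by a threshold column.
#'
#' @param roc Output of [roc_scan()].
#' @param colour_by Optional column name used for colour.
#' @return A ggplot.
#' @export
plot_roc <- function(roc, colour_by = NULL) {
  p <- ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::aes(colour = factor(.data[[colour_by]]))
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_path() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Heat map of filter-overlap ratios
#'
#' @param overlap Output of [filter_overlap_matrix()].
#' @return A ggplot.
#' @export
plot_filter_overlap <- function(overlap) {
  ggplot2::ggplot(
    overlap,
    ggplot2::aes(x = .data$filter_i, y = .data$filter_j,
                 fill = .data$ratio)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$ratio), "-",
                     sprintf("%.2f", .data$ratio))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "obs/exp") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heat map of subset pass percentages per filter
#'
#' @param pass_table Output of [subset_pass_table()].
#' @return A ggplot.
#' @export
plot_subset_heatmap <- function(pass_table) {
  ggplot2::ggplot(
    pass_table,
    ggplot2::aes(x = .data$subset, y = .data$filter,
                 fill = .data$pct_pass)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%",
                                                    .data$pct_pass)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 50,
                                  limits = c(0, 100)) +
    ggplot2::labs(x = "subset", y = NULL, fill = "% pass") +
    ggplot2::theme_minimal()
}

#' Heat map of GO fold enrichment across filters
#'
#' @param folds Tibble combining [go_fold_enrichment()] outputs with a
#'   `filter` column.
#' @param fold_hi,fold_lo Highlight thresholds for enrichment / depletion.
#' @return A ggplot.
#' @export
plot_go_heatmap <- function(folds, fold_hi = 3, fold_lo = 0.75) {
  ggplot2::ggplot(
    folds,
    ggplot2::aes(x = .data$filter, y = .data$term_id, fill = .data$fold)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 1,
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "fold",
                  subtitle = sprintf(
                    "highlight: fold >= %g or <= %g", fold_hi, fold_lo
                  )) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
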