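# ggplot2 views of the package's result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed vs expected combination abundance
#'
#' Scatter of observed combination counts against their independence
#' expectations on log axes; combinations flagged at the q threshold are
#' highlighted.
#'
#' @param object A `coordination_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coordination_test
#' @export
autoplot.coordination_test <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected_count + 0.5,
                                   y = .data$observed + 0.5,
                                   colour = .data$flagged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected count + 0.5 (independence)",
                  y = "observed count + 0.5",
                  colour = paste0("q ≤ ", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Per-cluster exon usage
#'
#' @param marginals A `marginal_freqs` tibble.
#' @return A ggplot of variant-use fractions, faceted by cluster.
#' @export
plot_exon_usage <- function(marginals) {
  ggplot2::ggplot(tibble::as_tibble(marginals),
                  ggplot2::aes(x = .data$variant_id, y = .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~cluster_id, scales = "free_x") +
    ggplot2::labs(x = "variant exon", y = "fraction of assigned reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Rank-abundance view of a count table
#'
#' @param object A `count_table`.
#' @param ... Unused.
#' @return A ggplot of counts by abundance rank (log y).
#' @method autoplot count_table
#' @export
autoplot.count_table <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::arrange(dplyr::desc(.data$count)) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "isoform rank", y = "read count") +
    ggplot2::theme_minimal()
}

#' Fold-compression distribution of a product index
#'
#' @param object A `compression_stats` tibble.
#' @param ... Unused.
#' @return A ggplot histogram of per-product fold compression.
#' @method autoplot compression_stats
#' @export
autoplot.compression_stats <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fold_compression)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "RNA span / product length", y = "products") +
    ggplot2::theme_minimal()
}
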