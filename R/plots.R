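#' Plot a taxon's spatial counts on the array grid
#'
#' @param matrix A [taxa_matrix()].
#' @param layout An [array_layout()] with the grid coordinates.
#' @param taxon Row to plot (default: highest-count taxon).
#' @return A ggplot object.
#' @export
plot_spatial_counts <- function(matrix, layout, taxon = NULL) {
  if (is.null(taxon)) taxon <- rownames(matrix)[which.max(rowSums(matrix))]
  df <- tibble(barcode = colnames(matrix),
               count = as.numeric(matrix[taxon, ])) |>
    dplyr::inner_join(as_tibble(as.data.frame(layout)), by = "barcode")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = taxon, x = "grid x", y = "grid y",
                  colour = "molecules") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot posterior characteristic expression per MROI
#'
#' Posterior means and 90% intervals of the condition-level (level-1)
#' characteristic expression coefficients.
#'
#' @param object A `splotch_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splotch_fit <- function(object, ...) {
  td <- tidy(object, pars = "^beta1\\[")
  td$group <- sub("^beta1\\[([^,]+),.*$", "\\1", td$term)
  td$mroi <- sub("^beta1\\[[^,]+,(.*)\\]$", "\\1", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mroi, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(title = object$taxon, x = "MROI",
                  y = "characteristic expression (log rate)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot deep-classifier training history
#'
#' @param model A fitted `deep_taxa_model`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history)) stop("model has no training history")
  df <- tidyr::pivot_longer(model$history, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
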