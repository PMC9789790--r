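#' Plot the fitted dropout curve over per-gene statistics
#'
#' Scatter of dropout rate against mean expression with the fitted
#' Michaelis-Menten curve `P = K_M / (E + K_M)` overlaid.
#'
#' @param stats Tibble from [compute_dropout_stats()] (tested or not).
#' @param fit An `mm_dropout_fit`.
#' @return A ggplot object.
#' @export
plot_dropout_fit <- function(stats, fit) {
  grid <- tibble::tibble(
    E = exp(seq(log(max(min(stats$E[stats$E > 0]), 1e-3)),
                log(max(stats$E)), length.out = 200))
  )
  grid$P <- fit$K_M / (grid$E + fit$K_M)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$E, y = .data$P)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean expression E", y = "dropout rate P",
                  title = sprintf("Michaelis-Menten dropout fit (K_M = %.3g)",
                                  fit$K_M)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mm_dropout_fit <- function(object, stats, ...) {
  plot_dropout_fit(stats, object)
}

#' Spatial map of one cell type's predicted proportion
#'
#' @param props A [proportion_matrix()].
#' @param coords Matching [spot_coordinates()].
#' @param type Cell type to map (defaults to the first).
#' @return A ggplot object.
#' @export
plot_spatial_proportions <- function(props, coords,
                                     type = colnames(props)[1]) {
  df <- tidy.proportion_matrix(props) |>
    dplyr::filter(.data$cell_type == type) |>
    dplyr::inner_join(coords, by = "obs_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$proportion)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Predicted proportion:", type)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.proportion_matrix <- function(object, ...) {
  df <- tidy.proportion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$obs_id, y = .data$proportion,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "spot", y = "proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.gcn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "set",
                            values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "GCN training", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.autoencoder <- function(object, ...) {
  ggplot2::ggplot(object$loss_log,
                  ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Autoencoder training",
                  y = "reconstruction MSE") +
    ggplot2::theme_minimal()
}
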