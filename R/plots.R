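#' Plot a fair Gibbs clustering fit
#'
#' Scatter of the first two features, colored by MAP cluster, shaped by the
#' protected attribute, with point transparency tracking the
#' misclassification probability (uncertain allocations fade out).
#'
#' @param object A [fair_gibbs()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fair_gibbs <- function(object, ...) {
  td <- tidy(object)
  f <- object$dataset$features
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data[[f[1]]], y = .data[[f[2]]],
    colour = factor(.data$map_cluster),
    shape = .data[[object$dataset$attribute]],
    alpha = 1 - .data$misclassification
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_continuous(range = c(0.3, 1), guide = "none") +
    ggplot2::labs(colour = "MAP cluster",
                  shape = object$dataset$attribute,
                  title = sprintf("Fair Gibbs clustering (K = %d, balance %.2f)",
                                  object$config$K,
                                  object$summary$balance_map)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the posterior co-clustering matrix
#'
#' Observations are ordered by the least-squares partition so blocks of high
#' co-clustering probability line up with the point-estimate clusters.
#'
#' @param fit A [fair_gibbs()] or [gibbs_kmeans()] fit.
#' @return A ggplot object.
#' @export
plot_coclustering <- function(fit) {
  eta <- fit$summary$coclustering
  ord <- order(fit$summary$ls_partition)
  m <- eta[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$probability <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "P(co-clustered)") +
    ggplot2::theme_minimal()
}
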