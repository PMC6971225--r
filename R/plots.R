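#' @export
autoplot.afferent_trace <- function(object, ...) {
  if (is.null(object$trace)) abort("trace was not retained (return_trace = FALSE)")
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$time_ms, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(
      data = tibble(time_ms = object$spike_times,
                    v = rep(object$params$v_peak, length(object$spike_times))),
      colour = "red", size = 0.8
    ) +
    ggplot2::labs(
      x = "time (ms)", y = "membrane potential (mV)",
      title = sprintf("%s %s-I (%s arithmetic)", object$params$model,
                      object$config$afferent_type, object$arithmetic)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spike_raster <- function(object, ...) {
  pop <- attr(object, "population")
  df <- mutate(object,
               type = factor(.data$type, levels = c("SA", "FA"),
                             labels = c("SA-I", "FA-I")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spike_time_ms / 1000,
                                   y = .data$afferent_idx,
                                   colour = factor(.data$sensor))) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$type), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "time (s)", y = "afferent", colour = "sensor") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_eval <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$fingers),
                               y = .data$mean_accuracy,
                               fill = .data$afferent_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = pmin(.data$mean_accuracy + .data$sd_accuracy, 1)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "engaged fingers", y = "classification accuracy",
                  fill = "afferents") +
    ggplot2::theme_minimal()
}

#' Scatter the first principal components of a feature matrix
#'
#' @param features A `feature_matrix` from [spike_counts()].
#' @param n_components Components to compute (first two are plotted).
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(features, n_components = 3) {
  sc <- reduce_pca(features, n_components = n_components)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$object,
                                   shape = factor(.data$fingers))) +
    ggplot2::geom_point() +
    ggplot2::labs(shape = "fingers") +
    ggplot2::theme_minimal()
}
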