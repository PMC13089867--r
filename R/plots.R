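#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an RDM
#'
#' @param object An [rdm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- expand.grid(state_a = 1:4, state_b = 1:4)
  m <- unclass(object)
  df$dissimilarity <- m[cbind(df$state_a, df$state_b)]
  ggplot2::ggplot(df, ggplot2::aes(.data$state_b, .data$state_a,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2g", .data$dissimilarity)),
                       size = 3) +
    ggplot2::scale_y_reverse(breaks = 1:4, labels = paste0("S", 1:4)) +
    ggplot2::scale_x_continuous(breaks = 1:4, labels = paste0("S", 1:4),
                                position = "top") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "type") %||% "", " RDM")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Lateralization timecourse with cluster shading
#'
#' Plots the per-timepoint group t statistic of the state-2 minus state-3
#' horizontal gaze difference, the cluster-forming threshold, and shades
#' significant cluster windows.
#'
#' @param object A [cluster_permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(time_ms = object$time_ms, t = object$tvals)
  sig <- object$clusters[object$clusters$p < object$alpha, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$t))
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25)
  }
  p +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "one-sample t (rightward shift)") +
    ggplot2::theme_minimal()
}

#' Per-condition gaze timecourses
#'
#' @param timecourses Tibble from [condition_timecourses()].
#' @param axis `"x"` or `"y"`.
#' @return A ggplot object.
#' @export
plot_gaze_timecourses <- function(timecourses, axis = c("x", "y")) {
  axis <- match.arg(axis)
  ggplot2::ggplot(timecourses,
                  ggplot2::aes(.data$time_ms, .data[[axis]],
                               colour = factor(.data$condition))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = paste("median gaze", axis, "(px)"),
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Per-subject model correlations of an RSA result
#'
#' @param object An [rsa_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$subjects, c("r", "partial_r"),
                            names_to = "kind", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$kind, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "model correlation",
                  title = paste("model:", object$model)) +
    ggplot2::theme_minimal()
}
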