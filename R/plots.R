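#' Scatterplot of two gradients colored by network
#'
#' The classic gradient geometry plot: each ROI placed by two gradient
#' coordinates, colored by its network, so hierarchy compression is visible
#' as vertices of the point cloud moving together.
#'
#' @param object A `gradient_set`.
#' @param partition Named character vector mapping ROI to network (optional).
#' @param gx,gy Gradient indices for the x and y axes (default G2 vs G1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_set <- function(object, partition = NULL, gx = 2, gy = 1, ...) {
  df <- tibble(roi = rownames(object$coords),
               x = object$coords[, gx], y = object$coords[, gy])
  if (!is.null(partition)) df$network <- partition[df$roi]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = paste0("G", gx), y = paste0("G", gy))
  if (is.null(partition)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$network), alpha = 0.8)
  }
}

#' Step profiles of an SFC map
#'
#' Degree (raw or normalized) per ROI across steps, one line per ROI, a
#' quick visual check of convergence toward the transmodal pattern.
#'
#' @param object An `sfc_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_map <- function(object, ...) {
  tidy.sfc_map(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$degree,
                                 group = .data$roi)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "step", y = if (object$normalized) "normalized degree"
                  else "walk count")
}

#' Heatmap of brain-language prediction z values
#'
#' Displays the output of [brainlang_glm()] as a measure-by-dispersion
#' heatmap; only cells significant after FDR correction are filled.
#'
#' @param results Tibble from [brainlang_glm()].
#' @param q_threshold Transparency cutoff (default 0.05).
#' @return A ggplot object.
#' @export
plot_brainlang <- function(results, q_threshold = 0.05) {
  results |>
    dplyr::mutate(z_sig = ifelse(.data$q < q_threshold, .data$z, NA_real_)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$dispersion, y = .data$measure,
                                 fill = .data$z_sig)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "white", name = "z") +
    ggplot2::labs(x = NULL, y = NULL)
}
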