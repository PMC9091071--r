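#' Plot a slice with its annotations and detections
#'
#' @param slice An [annotated_slice()].
#' @param detections Optional detection tibble for this slice.
#' @return A ggplot object: the image raster, ground-truth boxes in yellow,
#'   detections colored by predicted class.
#' @export
plot_slice <- function(slice, detections = NULL) {
  img <- slice_image(slice)
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$v <- as.numeric(img)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(slice$boxes) > 0L)
    p <- p + ggplot2::geom_rect(
      data = slice$boxes,
      ggplot2::aes(xmin = .data$x0 + 0.5, xmax = .data$x1 + 0.5,
                   ymin = .data$y0 + 0.5, ymax = .data$y1 + 0.5),
      color = "yellow", fill = NA, linewidth = 0.6)
  if (!is.null(detections) && nrow(detections) > 0L) {
    detections$class <- ifelse(detections$s_malignant >= detections$s_benign,
                               "malignant", "benign")
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$x0 + 0.5, xmax = .data$x1 + 0.5,
                   ymin = .data$y0 + 0.5, ymax = .data$y1 + 0.5,
                   color = .data$class),
      fill = NA, linewidth = 0.6, linetype = 2) +
      ggplot2::scale_color_manual(values = c(benign = "green", malignant = "red"))
  }
  p
}

#' @rdname evaluate_wff
#' @param object A `wff_eval`.
#' @export
autoplot.wff_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$malignancy_score,
                                  fill = .data$true_class)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "fused malignancy score", y = "patients",
                  fill = "true class")
}

#' Plot an ablation table
#'
#' @param ablation Output of [ablation_report()].
#' @return Bar chart of the four metrics per fusion strategy.
#' @export
plot_ablation <- function(ablation) {
  long <- tidyr::pivot_longer(ablation[, c("strategy", "ACC", "SE", "SP", "AUC")],
                              -"strategy", names_to = "metric",
                              values_to = "value")
  long$strategy <- factor(long$strategy, levels = ablation$strategy)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
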