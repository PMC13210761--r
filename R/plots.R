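# ggplot2 visualizations for windows, asymmetry, confusion matrices,
# training history and the Polygon Area Metric hexagon.

#' Plot one stroke window's 12 channels
#'
#' @param tensor A [window_tensor].
#' @param i Window index.
#' @return A ggplot object (channels faceted by wrist and modality).
#' @export
plot_window <- function(tensor, i = 1L) {
  w <- tensor_window(tensor, i)
  layout <- channel_layout()
  df <- tibble::as_tibble(w) |>
    dplyr::mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-"sample", names_to = "channel") |>
    dplyr::left_join(layout, by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 41, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(modality ~ wrist, scales = "free_y") +
    ggplot2::labs(x = "sample (60 Hz)", y = "signal",
                  title = paste0("Stroke window ", i,
                                 " (impact at sample 41)")) +
    ggplot2::theme_minimal()
}

#' Asymmetry-index distribution by skill group
#'
#' @param asin_tbl Output of [asymmetry_index()] on a tensor (needs `skill`
#'   and `asin` columns).
#' @return A ggplot boxplot.
#' @export
plot_asymmetry <- function(asin_tbl) {
  ggplot2::ggplot(asin_tbl, ggplot2::aes(x = .data$skill, y = .data$asin,
                                         fill = .data$skill)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Asymmetry Index",
                  title = "Bilateral asymmetry by expertise") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot
#'
#' @param cm A `confusion_result`.
#' @return A ggplot tile plot with counts.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(cm$table))
  names(df) <- c("truth", "prediction", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Accuracy %.3f", cm$accuracy)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_confusion
#' @param object A `confusion_result`.
#' @param ... Unused.
#' @export
autoplot.confusion_result <- function(object, ...) plot_confusion(object)

#' Training-history curve
#'
#' @param model A trained `stroke_model`.
#' @return A ggplot of per-epoch training loss (and validation accuracy when
#'   recorded).
#' @export
plot_history <- function(model) {
  h <- model$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#27408B") +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
  if (any(!is.na(h$val_accuracy))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_accuracy),
                                colour = "#2E8B57", linetype = "dashed")
  }
  p
}

#' @rdname plot_history
#' @param object A `stroke_model`.
#' @param ... Unused.
#' @export
autoplot.stroke_model <- function(object, ...) plot_history(object)

#' Polygon Area Metric radar hexagon
#'
#' @param object A `pam_score`.
#' @param ... Unused.
#' @return A ggplot hexagon radar chart.
#' @export
autoplot.pam_score <- function(object, ...) {
  ang <- pi / 2 - (0:5) * pi / 3
  df <- tibble::tibble(
    metric = names(object$metrics),
    r = object$metrics,
    x = object$metrics * cos(ang), y = object$metrics * sin(ang),
    xg = cos(ang), yg = sin(ang)
  )
  closed <- dplyr::bind_rows(df, df[1, ])
  ggplot2::ggplot(closed) +
    ggplot2::geom_polygon(ggplot2::aes(x = .data$xg, y = .data$yg),
                          fill = NA, colour = "grey60", linetype = "dashed") +
    ggplot2::geom_polygon(ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "#27408B", alpha = 0.4, colour = "#27408B") +
    ggplot2::geom_text(data = df,
                       ggplot2::aes(x = 1.15 * .data$xg, y = 1.15 * .data$yg,
                                    label = .data$metric)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("PAM = %.3f", object$pam)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
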