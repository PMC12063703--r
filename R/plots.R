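# Plotting helpers (ggplot2 is suggested, not required).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot a training-loss trajectory
#'
#' Works on the `$log` tibble of [train_source()], [train_alignment()] or
#' [adapt()] (columns `epoch`/`step` and `loss`).
#'
#' @param log A tibble with a `loss` column and `step` or `epoch`.
#' @return A ggplot object.
#' @export
plot_training_log <- function(log) {
  need_ggplot()
  xvar <- if ("step" %in% names(log)) "step" else "epoch"
  ggplot2::ggplot(log, ggplot2::aes(.data[[xvar]], .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = "loss") +
    ggplot2::theme_minimal()
}

#' Display a phantom slice with its labels, prompt, or prediction
#'
#' @param image Numeric matrix (image, prompt, ...), or integer label mask.
#' @param title Plot title.
#' @return A ggplot object (tile heatmap in image orientation).
#' @export
plot_slice <- function(image, title = NULL) {
  need_ggplot()
  df <- data.frame(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    value = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
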