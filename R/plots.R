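# autoplot() methods: mid-grid slices for tensors, training curves for
# fits, per-structure summaries for evaluation tables.

#' Plot an axial slice of a feature grid channel
#'
#' @param object A `feature_grid`.
#' @param channel Channel index 1..18 (default 2, the carbon one-hot).
#' @param z Slice index (default the middle of the grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_grid <- function(object, channel = 2L,
                                  z = ceiling(dim(object$tensor)[3] / 2),
                                  ...) {
  sl <- object$tensor[, , z, channel]
  df <- tidyr::expand_grid(
    x = seq_len(nrow(sl)), y = seq_len(ncol(sl))
  )
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("feature grid channel %d, slice z = %d", channel, z),
      fill = "sum"
    )
}

#' Plot an axial slice of a site mask or probability grid
#'
#' @param object A `site_mask`.
#' @param z Slice index (default middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_mask <- function(object,
                               z = ceiling(dim(object$tensor)[3] / 2),
                               ...) {
  sl <- object$tensor[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("site mask, slice z = %d", z),
      fill = "occupied")
}

#' Plot the training loss trace of a fit
#' @param object A `puresnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.puresnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
    ggplot2::aes(.data$step, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "gradient step",
      y = paste0(object$config$loss, " loss")
    )
}

#' Plot per-structure DCC values colored by evaluation class
#' @param records Tibble of evaluation records ([evaluate_structure()] rows).
#' @param threshold DCC cutoff drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_eval_records <- function(records, threshold = 4) {
  df <- records
  df$dcc_plot <- ifelse(is.na(df$dcc), Inf, df$dcc)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$structure_id, y = .data$dcc_plot, color = .data$class
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "DCC (Å)", color = "class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
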