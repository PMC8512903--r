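#' Heatmap of attention weights across clock time
#'
#' Renders the `observations x T` attention matrix as a heatmap with clock
#' time on the horizontal axis and timestep (1 = oldest, T = most recent) on
#' the vertical axis, optionally overlaying the most-highlighted-timestep
#' trace. Line segments of slope -1 in the trace show one piece of neural
#' activity staying highlighted while it recedes into the window.
#'
#' @param records Attention matrix (`N x T`) or list of attention vectors.
#' @param highlight Overlay the per-observation argmax trace (default
#'   `TRUE`).
#' @return A ggplot object.
#' @export
plot_attention <- function(records, highlight = TRUE) {
  am <- attention_matrix(records)
  mat <- am$matrix
  df <- data.frame(
    clock = rep(seq_len(nrow(mat)), times = ncol(mat)),
    timestep = rep(seq_len(ncol(mat)), each = nrow(mat)),
    weight = as.numeric(mat)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$clock, y = .data$timestep,
                                        fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "attention") +
    ggplot2::labs(x = "clock time (observation)", y = "timestep") +
    ggplot2::theme_minimal()
  if (highlight) {
    tr <- data.frame(clock = seq_along(am$argmax), timestep = am$argmax)
    p <- p + ggplot2::geom_point(
      data = tr, ggplot2::aes(x = .data$clock, y = .data$timestep),
      inherit.aes = FALSE, colour = "white", size = 0.3
    )
  }
  p
}
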