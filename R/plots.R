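# ggplot2 helpers (ggplot2 is suggested, not required).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_fmt("plotting requires the 'ggplot2' package")
  }
}

#' Plot one z-slice of a volume
#'
#' @param volume a [volume3d()].
#' @param z 0-based slice index (default: middle slice).
#' @param overlay optional second [volume3d()] (e.g. a prediction) drawn as
#'   translucent fill over the slice.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL, overlay = NULL) {
  need_ggplot()
  d <- dim(volume$data)
  z <- z %||% (d[3] %/% 2)
  sl <- volume$data[, , z + 1]
  df <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1)
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "density")
  if (!is.null(overlay)) {
    df$pred <- as.vector(overlay$data[, , z + 1])
    p <- p + ggplot2::geom_raster(
      data = df[df$pred > 0.05, , drop = FALSE],
      ggplot2::aes(alpha = .data$pred), fill = "red") +
      ggplot2::scale_alpha(range = c(0, 0.8))
  }
  p
}

#' Plot a model's training loss curve
#'
#' @param object a trained `seg_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_model <- function(object, ...) {
  need_ggplot()
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = sprintf("%s '%s'", object$arch_name,
                                  object$feature_name))
}
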