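#' Interpolate per-channel scores over the scalp
#'
#' Inverse-distance-weighted interpolation of channel scores onto a square
#' grid masked to the unit head circle: the interpolant approaches each
#' channel's score at its position (so extremes anchor at the electrodes)
#' and a constant score field stays exactly constant. Deterministic for
#' fixed inputs.
#'
#' @param scores Numeric vector, one score per montage channel.
#' @param montage A [generate_montage()] object.
#' @param grid_n Grid resolution per axis.
#' @param power Inverse-distance exponent.
#' @return A tibble with columns `x`, `y`, `value` (NA outside the head).
#' @export
interpolate_topography <- function(scores, montage, grid_n = 67,
                                   power = 3) {
  if (length(scores) != length(montage$names)) {
    stop("score length (", length(scores), ") does not match channel count (",
         length(montage$names), ")", call. = FALSE)
  }
  ax <- seq(-1, 1, length.out = grid_n)
  grid <- expand.grid(x = ax, y = ax)
  d2 <- outer(grid$x, montage$pos[, 1], "-")^2 +
        outer(grid$y, montage$pos[, 2], "-")^2
  wts <- (d2 + 1e-9)^(-power / 2)
  val <- drop(wts %*% scores) / rowSums(wts)
  val[grid$x^2 + grid$y^2 > 1] <- NA_real_
  tibble::tibble(x = grid$x, y = grid$y, value = val)
}

#' Plot a scalp topography
#'
#' @param scores Per-channel scores.
#' @param montage A [generate_montage()] object.
#' @param title Plot title.
#' @param grid_n,power Passed to [interpolate_topography()].
#' @return A ggplot object.
#' @export
plot_topography <- function(scores, montage, title = NULL, grid_n = 67,
                            power = 3) {
  df <- interpolate_topography(scores, montage, grid_n, power)
  chans <- tibble::tibble(x = montage$pos[, 1], y = montage$pos[, 2],
                          name = montage$names)
  theta <- seq(0, 2 * pi, length.out = 181)
  head <- tibble::tibble(x = cos(theta), y = sin(theta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value), na.rm = TRUE) +
    ggplot2::geom_path(data = head, linewidth = 0.6) +
    ggplot2::geom_point(data = chans, size = 0.8) +
    ggplot2::geom_text(data = chans, ggplot2::aes(label = .data$name),
                       size = 2, vjust = -1) +
    ggplot2::scale_fill_viridis_c(na.value = "transparent",
                                  name = "score") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(title)
}

#' Render a scalp topography to an image file
#'
#' Writes the interpolated map with fixed device settings so identical
#' inputs produce identical files.
#'
#' @param scores Per-channel scores.
#' @param montage A [generate_montage()] object.
#' @param file Output path (PNG).
#' @param ... Passed to [plot_topography()].
#' @return `file`, invisibly.
#' @export
render_topography <- function(scores, montage, file, ...) {
  p <- plot_topography(scores, montage, ...)
  grDevices::png(file, width = 600, height = 600, res = 100)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(file)
}
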