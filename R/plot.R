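# Slice visualisation: label image with the pulley circle and tangent
# construction overlaid, in the style of the study's annotated slice
# figures.

#' Plot a resampled slice with an optional tangent overlay
#'
#' @param x a `planar_slice` from [resample()].
#' @param construction optional [tangent_construction()] to overlay (MD
#'   line, proximal line, pulley circle, insertion points).
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.planar_slice <- function(x, construction = NULL, ...) {
  cols <- c("black", "firebrick", "forestgreen", "steelblue", "grey85")
  graphics::image(x$xs, x$ys, x$labels, col = cols, zlim = c(0, 4),
                  asp = 1, xlab = "x (mm, lateral +)",
                  ylab = "y (mm, along diaphysis)",
                  main = if (is.na(x$slice_label)) "" else x$slice_label,
                  ...)
  if (!is.null(construction)) {
    tc <- construction
    phi <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(tc$circle$center[1] + tc$circle$radius * cos(phi),
                    tc$circle$center[2] + tc$circle$radius * sin(phi),
                    col = "purple", lwd = 2)
    draw_line <- function(p, contact, col) {
      graphics::segments(p[1], p[2], contact[1], contact[2],
                         col = col, lwd = 2)
    }
    draw_line(tc$dip2d, tc$contact_md, "yellow")
    draw_line(tc$pip2d, tc$contact_prox, "orange")
    graphics::points(rbind(tc$dip2d, tc$pip2d), pch = 19, col = "white")
  }
  invisible(x)
}
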