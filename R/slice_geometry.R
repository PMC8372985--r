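# Tangent-line construction on a slice. The middle deltoid is a string on a
# pulley: the MD line runs from the distal insertion point (DIP) tangent to
# the in-plane implant circle; the proximal line runs from the slice's
# proximal insertion point (PIP) tangent to the same circle. E is the angle
# between the MD line and the humeral diaphysis axis, B the change of fiber
# direction at the pulley, and T = B/2.

#' Angle set measured on a slice
#'
#' @param E angle (degrees) between the MD line and the diaphysis axis;
#'   `0 <= E < 90`.
#' @param B angle (degrees) of the fiber's change of direction at the
#'   pulley; `0 < B < 180`. `T` is defined as `B / 2`.
#' @return An object of class `angle_set` with fields `E`, `B`, `T`.
#' @export
angle_set <- function(E, B) {
  stopifnot(is.finite(E), is.finite(B))
  if (E < 0 || E >= 90) stop("angle E must lie in [0, 90) degrees")
  if (B <= 0 || B >= 180) stop("angle B must lie in (0, 180) degrees")
  structure(list(E = E, B = B, T = B / 2), class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("<angle_set> E = %.2f, B = %.2f, T = %.2f degrees\n",
              x$E, x$B, x$T))
  invisible(x)
}

#' Diaphysis axis in slice coordinates
#'
#' The humeral diaphysis axis of a resampled slice: the plane frame is
#' built with its in-plane y axis parallel to the projected diaphysis
#' direction, so the axis runs through the centroid of the diaphysis label
#' with direction `(0, 1)`.
#'
#' @param slice a [resample()]d `planar_slice`.
#' @return a [line2d()].
#' @export
diaphysis_axis_2d <- function(slice) {
  stopifnot(inherits(slice, "planar_slice"))
  hit <- which(slice$labels == 4L, arr.ind = TRUE)
  if (nrow(hit) == 0) stop("no diaphysis pixels (label 4) in this slice")
  centroid <- c(mean(slice$xs[hit[, 1]]), mean(slice$ys[hit[, 2]]))
  line2d(centroid, c(0, 1))
}

#' Tangent-line construction for one slice
#'
#' Builds the MD line (external tangent from the projected DIP, wrapping
#' the lateral aspect of the pulley) and the proximal line (tangent from
#' the projected insertion site), both directed from their insertion
#' towards the pulley.
#'
#' @param circle the in-plane implant circle from [slice_circle()].
#' @param dip2d projected distal insertion point (length-2, mm).
#' @param pip2d projected proximal insertion point (length-2, mm).
#' @param axis the diaphysis axis as a [line2d()]; defaults to the frame's
#'   y axis through the origin.
#' @return An object of class `tangent_construction` with the two tangent
#'   [line2d()]s (`md_line`, `proximal_line`), their contact points,
#'   `dip2d`, `pip2d`, `circle` and `axis`.
#' @export
tangent_construction <- function(circle, dip2d, pip2d,
                                 axis = line2d(c(0, 0), c(0, 1))) {
  stopifnot(inherits(circle, "circle2d"), inherits(axis, "line2d"))
  md <- tangent_from_point(dip2d, circle, side = "left")
  prox <- tangent_from_point(pip2d, circle, side = "right")
  structure(list(md_line = md,
                 proximal_line = prox,
                 contact_md = attr(md, "contact"),
                 contact_prox = attr(prox, "contact"),
                 dip2d = as.numeric(dip2d),
                 pip2d = as.numeric(pip2d),
                 circle = circle,
                 diaphysis_axis = axis),
            class = "tangent_construction")
}

#' @export
print.tangent_construction <- function(x, ...) {
  cat(sprintf("<tangent_construction> pulley rho = %.2f mm at (%.2f, %.2f)\n",
              x$circle$radius, x$circle$center[1], x$circle$center[2]))
  invisible(x)
}

#' Measure the slice angles E, B and T
#'
#' `E` is the unsigned acute angle between the MD line and the diaphysis
#' axis. `B` is the unsigned angle between the two fiber directions taken
#' towards the pulley (distal insertion -> pulley and proximal insertion ->
#' pulley), i.e. the string's change of direction; `T = B / 2`.
#'
#' @param construction a [tangent_construction()].
#' @return an [angle_set()].
#' @export
measure_angles <- function(construction) {
  stopifnot(inherits(construction, "tangent_construction"))
  d1 <- construction$md_line$direction
  d2 <- construction$proximal_line$direction
  B <- direction_angle(d1, d2)
  if (B < 1e-9 || B > 180 - 1e-9) {
    stop("MD line and proximal line are parallel: no pulley deflection")
  }
  E <- line_angle(d1, construction$diaphysis_axis$direction)
  angle_set(E = E, B = B)
}
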