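# Low-level vector geometry shared by the fitting, reslicing and
# slice-measurement code. World coordinates are millimetres, X mediolateral
# (lateral positive, right-shoulder convention), Y parallel to the humeral
# diaphysis, Z completing a right-handed frame.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# z-component of the 2D cross product; sign tells which side of `a` the
# vector `b` lies on (positive = left of a).
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' In-plane circle
#'
#' A circle in slice (in-plane, mm) coordinates, typically the intersection
#' of the fitted implant sphere with a slice plane.
#'
#' @param center length-2 numeric, circle centre in mm.
#' @param radius positive circle radius in mm.
#' @return An object of class `circle2d`.
#' @export
circle2d <- function(center, radius) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2, is.finite(radius))
  if (radius <= 0) stop("circle radius must be positive")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "circle2d")
}

#' @export
print.circle2d <- function(x, ...) {
  cat(sprintf("<circle2d> center (%.3f, %.3f) mm, radius %.3f mm\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Directed line in slice coordinates
#'
#' @param point length-2 numeric, a point on the line (mm).
#' @param direction length-2 numeric direction; normalised internally.
#' @return An object of class `line2d` with unit `direction`.
#' @export
line2d <- function(point, direction) {
  point <- as.numeric(point)
  stopifnot(length(point) == 2, length(direction) == 2)
  structure(list(point = point, direction = vunit(as.numeric(direction))),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> through (%.3f, %.3f), direction (%.4f, %.4f)\n",
              x$point[1], x$point[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Perpendicular distance from a point to a line
#'
#' @param p length-2 numeric point (mm).
#' @param line a [line2d()].
#' @return distance in mm.
#' @export
point_line_distance <- function(p, line) {
  stopifnot(inherits(line, "line2d"))
  abs(cross2(line$direction, as.numeric(p) - line$point))
}

#' Tangent line from an external point to a circle
#'
#' Returns the directed tangent line through `p` touching `circle`, oriented
#' from `p` towards the contact point. Of the two tangents, `side` selects
#' the one with the circle centre on the requested side of the directed
#' line; for a right shoulder the deltoid wraps the glenosphere
#' counter-clockwise in slice coordinates, so the distal (MD) line uses
#' `side = "left"` and the proximal line (directed from the proximal
#' insertion towards the pulley) uses `side = "right"`.
#'
#' @param p length-2 numeric point outside the circle.
#' @param circle a [circle2d()].
#' @param side `"left"` or `"right"`: side of the directed line on which the
#'   circle centre lies.
#' @return a [line2d()] through `p` with attribute `contact`, the tangency
#'   point on the circle.
#' @export
tangent_from_point <- function(p, circle, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(circle, "circle2d"))
  p <- as.numeric(p)
  d <- circle$center - p
  L <- vnorm(d)
  if (L <= circle$radius + 1e-12) {
    stop("point lies inside or on the circle; no external tangent exists")
  }
  alpha <- asin(circle$radius / L)
  u <- d / L
  want <- if (side == "left") 1 else -1
  for (s in c(1, -1)) {
    t <- rot2(u, s * alpha)
    if (sign(cross2(t, d)) == want) {
      contact <- p + sqrt(L^2 - circle$radius^2) * t
      ln <- line2d(p, t)
      attr(ln, "contact") <- contact
      return(ln)
    }
  }
  stop("internal error: tangent side selection failed") # nocov
}

# Unsigned angle (degrees) between two unit directions, in [0, 180].
direction_angle <- function(u, v) {
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Acute unsigned angle (degrees) between two undirected lines, in [0, 90].
line_angle <- function(u, v) {
  rad2deg(acos(min(1, abs(sum(u * v)))))
}
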