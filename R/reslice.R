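# Anatomical plane slices. Each slice plane is defined by three landmarks:
# Point 1 = centre of the acromial reference sphere, Point 2 = an insertion
# site on the acromial arc, Point 3 = centre of the humeral diaphysis. The
# labeled volume is resampled into the plane with the cubic kernel
# w(t) = 2t^3 - 3t^2 + 1 over the 8 corner voxels of the enclosing cell.

#' Plane frame from three landmark points
#'
#' Builds the 4x4 homogeneous transform of a slice plane containing the
#' three points. The in-plane y axis is the projection of the humeral
#' diaphysis direction into the plane (so the diaphysis axis is a
#' coordinate axis of the slice), the origin is Point 3 and the in-plane x
#' axis is oriented so that lateral (world +X) maps to +x.
#'
#' @param p1,p2,p3 length-3 landmark points (mm): acromial sphere centre,
#'   insertion site, diaphysis centre.
#' @param ydir world direction of the humeral diaphysis (projected to give
#'   the in-plane y axis).
#' @param pixel_spacing slice raster spacing in mm (default 0.5).
#' @return An object of class `plane_frame` with fields `origin`, `x`, `y`,
#'   `normal` (unit 3-vectors), `matrix` (4x4 pixel->world transform) and
#'   `pixel_spacing`.
#' @export
plane_from_three_points <- function(p1, p2, p3, ydir = c(0, 1, 0),
                                    pixel_spacing = 0.5) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3,
            pixel_spacing > 0)
  n <- cross3(p2 - p1, p3 - p1)
  scale <- max(vnorm(p2 - p1), vnorm(p3 - p1), 1)
  if (vnorm(n) < 1e-9 * scale^2) {
    stop("the three landmark points are collinear; no plane is defined")
  }
  n <- vunit(n)
  yproj <- ydir - sum(ydir * n) * n
  if (vnorm(yproj) < 1e-9) {
    stop("diaphysis direction is perpendicular to the slice plane")
  }
  y <- vunit(yproj)
  x <- cross3(y, n)
  if (sum(x * c(1, 0, 0)) < 0) { # lateral (+X world) must map to +x
    x <- -x
    n <- -n
  }
  m <- diag(4)
  m[1:3, 1] <- x * pixel_spacing
  m[1:3, 2] <- y * pixel_spacing
  m[1:3, 3] <- n
  m[1:3, 4] <- p3
  structure(list(origin = p3, x = x, y = y, normal = n, matrix = m,
                 pixel_spacing = pixel_spacing,
                 points = rbind(p1, p2, p3)),
            class = "plane_frame")
}

#' @export
print.plane_frame <- function(x, ...) {
  cat(sprintf("<plane_frame> origin (%.2f, %.2f, %.2f) mm, normal (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Project world points into plane coordinates
#'
#' Orthogonal projection onto the plane, expressed in in-plane mm
#' coordinates (x lateral, y along the projected diaphysis axis, origin at
#' Point 3).
#'
#' @param frame a [plane_frame()].
#' @param p length-3 point or N x 3 matrix of world points (mm).
#' @return length-2 vector or N x 2 matrix of in-plane coordinates (mm).
#' @export
project_to_plane <- function(frame, p) {
  stopifnot(inherits(frame, "plane_frame"))
  if (is.matrix(p)) {
    rel <- sweep(p, 2, frame$origin)
    cbind(rel %*% frame$x, rel %*% frame$y)
  } else {
    rel <- as.numeric(p) - frame$origin
    c(sum(rel * frame$x), sum(rel * frame$y))
  }
}

#' Map in-plane mm coordinates back to world coordinates
#'
#' @param frame a [plane_frame()].
#' @param xy length-2 vector or N x 2 matrix of in-plane coordinates (mm).
#' @return length-3 vector or N x 3 matrix of world points on the plane.
#' @export
plane_to_world <- function(frame, xy) {
  stopifnot(inherits(frame, "plane_frame"))
  if (is.matrix(xy)) {
    t(frame$origin + outer(frame$x, xy[, 1]) + outer(frame$y, xy[, 2]))
  } else {
    frame$origin + xy[1] * frame$x + xy[2] * frame$y
  }
}

# Signed distance of world points from the plane.
plane_offset <- function(frame, p) {
  if (is.matrix(p)) {
    as.numeric(sweep(p, 2, frame$origin) %*% frame$normal)
  } else {
    sum((as.numeric(p) - frame$origin) * frame$normal)
  }
}

#' Cubic resampling kernel
#'
#' The interpolation weight `w(t) = 2t^3 - 3t^2 + 1` applied to the
#' normalised per-axis distance `t` (clamped to `[0, 1]`) between a slice
#' pixel and a neighbouring voxel centre. Satisfies `w(0) = 1`, `w(1) = 0`
#' and the partition of unity `w(t) + w(1 - t) = 1`.
#'
#' @param t numeric vector of normalised distances.
#' @return numeric vector of weights.
#' @export
cubic_weight <- function(t) {
  t <- pmin(1, pmax(0, t))
  2 * t^3 - 3 * t^2 + 1
}

#' Intersect a sphere with a slice plane
#'
#' @param sph a [sphere()].
#' @param frame a [plane_frame()].
#' @return a [circle2d()] in plane coordinates with attribute
#'   `plane_distance`, the distance `d` from the sphere centre to the
#'   plane; the radius is `sqrt(r^2 - d^2)`.
#' @export
slice_circle <- function(sph, frame) {
  stopifnot(inherits(sph, "sphere"), inherits(frame, "plane_frame"))
  d <- plane_offset(frame, sph$center)
  if (abs(d) >= sph$radius) {
    stop(sprintf(
      "plane misses the sphere: |distance| = %.3f mm >= radius %.3f mm",
      abs(d), sph$radius))
  }
  circ <- circle2d(project_to_plane(frame, sph$center),
                   sqrt(sph$radius^2 - d^2))
  attr(circ, "plane_distance") <- abs(d)
  circ
}

#' Candidate insertion points along the acromial arc
#'
#' Walks the acromial arc in `step_degrees` increments, producing the
#' candidate Point-2 positions from which the four Sakoma insertion sites
#' are selected.
#'
#' @param arc an acromial arc description: a list with `center` (length-3,
#'   mm), `radius` (mm), and `span` (length-2 arc angles in degrees); the
#'   arc lies in the axial plane through `center`. See [acromial_arc()].
#' @param step_degrees positive angular step (default 10).
#' @return A tibble with columns `arc_index` (0-based), `angle_deg` and the
#'   world coordinates `x`, `y`, `z`.
#' @export
insertion_points <- function(arc, step_degrees = 10) {
  if (step_degrees <= 0) stop("step_degrees must be positive")
  stopifnot(is.list(arc), length(arc$span) == 2)
  if (diff(arc$span) < 30) {
    stop("acromial arc span must cover at least 30 degrees")
  }
  ang <- seq(arc$span[1], arc$span[2], by = step_degrees)
  th <- deg2rad(ang)
  tibble::tibble(
    arc_index = seq_along(ang) - 1L,
    angle_deg = ang,
    x = arc$center[1] + arc$radius * cos(th),
    y = arc$center[2],
    z = arc$center[3] + arc$radius * sin(th))
}

#' Resample a labeled volume into a slice plane
#'
#' Every output pixel is a normalised weighted combination of the 8 corner
#' voxels of its enclosing cell, with per-axis weights
#' `w(t) = 2t^3 - 3t^2 + 1` (`t` the per-axis distance normalised by the
#' voxel spacing) multiplied across axes. The intensity channel
#' interpolates voxel values directly; the label channel takes the label
#' with the largest accumulated weight (weighted majority), with background
#' winning ties.
#'
#' @param volume a [labeled_volume()].
#' @param frame a [plane_frame()].
#' @param extent in-plane extent in mm (scalar or length-2, default 160).
#' @param center in-plane centre of the raster in mm (default `c(0, 40)`,
#'   roughly mid-way between the diaphysis origin and the acromion).
#' @return An object of class `planar_slice` with fields `image` (interp
#'   intensity), `labels` (integer label image), `xs`, `ys` (pixel centre
#'   coordinates in mm), and `frame`.
#' @export
resample <- function(volume, frame, extent = 160, center = c(0, 40)) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(frame, "plane_frame"))
  if (length(extent) == 1) extent <- c(extent, extent)
  ps <- frame$pixel_spacing
  xs <- seq(center[1] - extent[1] / 2 + ps / 2, center[1] + extent[1] / 2, by = ps)
  ys <- seq(center[2] - extent[2] / 2 + ps / 2, center[2] + extent[2] / 2, by = ps)
  npx <- length(xs); npy <- length(ys)
  grid <- cbind(rep(xs, times = npy), rep(ys, each = npx))
  world <- plane_to_world(frame, grid)
  # continuous 0-based voxel index
  idx <- sweep(sweep(world, 2, volume$origin), 2, volume$spacing, "/")
  dims <- dim(volume$voxels)
  i0 <- floor(idx)
  tfrac <- idx - i0
  inside <- i0[, 1] >= 0 & i0[, 1] <= dims[1] - 2 &
    i0[, 2] >= 0 & i0[, 2] <= dims[2] - 2 &
    i0[, 3] >= 0 & i0[, 3] <= dims[3] - 2
  if (!any(inside)) stop("slice plane lies entirely outside the volume")
  n <- nrow(grid)
  value <- rep(NA_real_, n)
  labs <- sort(unique(as.integer(volume$voxels)))
  mass <- matrix(0, n, length(labs))
  acc <- rep(0, n)
  wsum <- rep(0, n)
  vox <- volume$voxels
  ii <- which(inside)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- cubic_weight(abs(tfrac[ii, 1] - dx)) *
      cubic_weight(abs(tfrac[ii, 2] - dy)) *
      cubic_weight(abs(tfrac[ii, 3] - dz))
    lin <- (i0[ii, 1] + dx) + dims[1] * ((i0[ii, 2] + dy) +
                                           dims[2] * (i0[ii, 3] + dz)) + 1
    v <- vox[lin]
    acc[ii] <- acc[ii] + w * v
    wsum[ii] <- wsum[ii] + w
    col <- match(v, labs)
    mi <- cbind(ii, col)
    mass[mi] <- mass[mi] + w
  }
  value[ii] <- acc[ii] / wsum[ii]
  label_img <- rep(0L, n)
  label_img[ii] <- labs[max.col(mass[ii, , drop = FALSE], ties.method = "first")]
  structure(list(
    image = matrix(value, npx, npy),
    labels = matrix(label_img, npx, npy),
    xs = xs, ys = ys, frame = frame,
    circle = NULL, slice_label = NA_character_),
    class = "planar_slice")
}

#' @export
print.planar_slice <- function(x, ...) {
  cat(sprintf("<planar_slice>%s %d x %d pixels (%.2f mm), labels: %s\n",
              if (is.na(x$slice_label)) "" else paste0(" ", x$slice_label),
              length(x$xs), length(x$ys), x$frame$pixel_spacing,
              paste(sort(unique(as.integer(x$labels))), collapse = " ")))
  invisible(x)
}
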