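# Implant least-squares sphere (ILSS) fitting. The interactive protocol it
# automates: fit a sphere to operator-picked points on the internal aspect
# of the middle deltoid, drop points whose surface normal disagrees with the
# sphere normal, then repeatedly drop the 10% of points farthest from the
# sphere surface (dist^2 = |  ||p - cent||^2 - r^2 |) and refit.

#' Sphere in world coordinates
#'
#' @param center length-3 numeric centre (mm).
#' @param radius positive radius (mm).
#' @return An object of class `sphere` with fields `center` and `radius`.
#' @export
sphere <- function(center, radius) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)), is.finite(radius))
  if (radius <= 0) stop("sphere radius must be positive")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "sphere")
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf("<sphere> center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Oriented point cloud
#'
#' Points with unit surface normals, as produced by picking points on the
#' internal aspect of a segmented structure.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param normals optional N x 3 matrix of unit normals.
#' @param label structure tag, e.g. `"deltoid"`.
#' @return An object of class `oriented_cloud`.
#' @export
oriented_cloud <- function(points, normals = NULL, label = "") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(identical(dim(normals), dim(points)))
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) {
      stop("normals must be unit length (within 1e-6)")
    }
  }
  structure(list(points = points, normals = normals, label = label),
            class = "oriented_cloud")
}

#' @export
print.oriented_cloud <- function(x, ...) {
  cat(sprintf("<oriented_cloud> '%s': %d points%s\n", x$label,
              nrow(x$points), if (is.null(x$normals)) "" else " with normals"))
  invisible(x)
}

cloud_points <- function(x) {
  if (inherits(x, "oriented_cloud")) x$points else as.matrix(x)
}

subset_cloud <- function(cloud, keep) {
  oriented_cloud(cloud$points[keep, , drop = FALSE],
                 if (is.null(cloud$normals)) NULL else
                   cloud$normals[keep, , drop = FALSE],
                 cloud$label)
}

# Algebraic residual |  ||p-c||^2 - r^2 | per point, the "distance" used by
# the pruning rule.
sphere_dist2 <- function(points, sph) {
  abs(rowSums(sweep(points, 2, sph$center)^2) - sph$radius^2)
}

# Sum over points of the squared algebraic residual; the loss the linearised
# fit minimises, tracked for the convergence diagnostics.
sphere_algebraic_loss <- function(points, sph) {
  sum(sphere_dist2(points, sph)^2)
}

fit_sphere_algebraic <- function(points) {
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4) {
    stop("degenerate point set (coplanar or coincident); cannot fit a sphere")
  }
  beta <- qr.coef(qrA, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate sphere fit: non-positive squared radius")
  }
  sphere(center, sqrt(r2))
}

# Gauss-Newton refinement of the geometric loss sum((||p-c|| - r)^2); for a
# fixed centre the optimal radius is the mean distance, so only the centre
# is iterated.
refine_sphere_geometric <- function(points, sph, max_iter = 25,
                                    tol = 1e-12) {
  center <- sph$center
  for (i in seq_len(max_iter)) {
    d <- sweep(points, 2, center)
    dist <- sqrt(rowSums(d^2))
    if (any(dist < 1e-9)) break
    r <- mean(dist)
    u <- d / dist
    f <- dist - r
    J <- -sweep(u, 2, colMeans(u))
    JtJ <- crossprod(J)
    if (rcond(JtJ) < 1e-14) break
    step <- solve(JtJ, crossprod(J, f))
    center <- center - as.numeric(step)
    if (sqrt(sum(step^2)) < tol * (1 + r)) break
  }
  dist <- sqrt(rowSums(sweep(points, 2, center)^2))
  sphere(center, mean(dist))
}

#' Least-squares sphere fit
#'
#' Linearised algebraic fit (minimising `sum((||p-c||^2 - r^2)^2)`) followed
#' by Gauss-Newton refinement of the geometric loss
#' `sum((||p-c|| - r)^2)`. Exact on noiseless spherical data.
#'
#' @param cloud an [oriented_cloud()] or an N x 3 point matrix (N >= 4,
#'   non-coplanar).
#' @param refine logical; run the geometric refinement (default `TRUE`).
#' @return a [sphere()].
#' @export
fit_sphere_lsq <- function(cloud, refine = TRUE) {
  points <- cloud_points(cloud)
  sph <- fit_sphere_algebraic(points)
  if (refine) sph <- refine_sphere_geometric(points, sph)
  sph
}

#' Fitting configuration for the iterative ILSS loop
#'
#' @param prune_fraction fraction of points (by largest algebraic residual)
#'   removed at each iteration; the interactive protocol removes 10% per
#'   click.
#' @param max_iterations maximum fit/filter/prune iterations.
#' @param radius_tol convergence tolerance on the fitted radius (mm).
#' @param normal_sign `"inward"` if internal-aspect normals point towards
#'   the implant centre (the default convention), `"outward"` otherwise.
#' @param prune logical; disable to run normal filtering and a single fit
#'   only (used for the acromial reference sphere).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(prune_fraction = 0.10, max_iterations = 5,
                       radius_tol = 0.05,
                       normal_sign = c("inward", "outward"),
                       prune = TRUE) {
  normal_sign <- match.arg(normal_sign)
  stopifnot(prune_fraction >= 0, prune_fraction < 1, max_iterations >= 1,
            radius_tol > 0)
  structure(list(prune_fraction = prune_fraction,
                 max_iterations = max_iterations,
                 radius_tol = radius_tol,
                 normal_sign = normal_sign,
                 prune = prune),
            class = "fit_config")
}

#' Filter points by normal-vector agreement with a sphere
#'
#' Implements the elimination rule: a point is dropped when the scalar
#' product between its surface normal and the direction from the sphere
#' centre to the point is positive (for the `"inward"` convention, i.e. the
#' normal fails to point back towards the centre). `"outward"` flips the
#' test.
#'
#' @param cloud an [oriented_cloud()] with normals.
#' @param sph a [sphere()].
#' @param config a [fit_config()]; only `normal_sign` is used.
#' @return the retained [oriented_cloud()], with attribute `eliminated`
#'   giving the number of removed points.
#' @export
filter_by_normal <- function(cloud, sph, config = fit_config()) {
  stopifnot(inherits(cloud, "oriented_cloud"), inherits(sph, "sphere"))
  if (is.null(cloud$normals)) return(structure(cloud, eliminated = 0L))
  outward <- sweep(cloud$points, 2, sph$center)
  dp <- rowSums(cloud$normals * outward)
  keep <- if (config$normal_sign == "inward") dp <= 0 else dp >= 0
  if (!any(keep)) {
    stop("all points eliminated by the normal filter; the normal_sign ",
         "convention ('", config$normal_sign, "') is inconsistent with ",
         "this cloud")
  }
  structure(subset_cloud(cloud, keep), eliminated = sum(!keep))
}

#' Prune the points farthest from a sphere surface
#'
#' Removes `ceiling(fraction * N)` points with the largest
#' `dist^2 = |  ||p - cent||^2 - r^2 |`, breaking ties by original index.
#'
#' @param cloud an [oriented_cloud()].
#' @param sph a [sphere()].
#' @param fraction fraction in `[0, 1)` of points to remove.
#' @return the retained [oriented_cloud()].
#' @export
prune_farthest <- function(cloud, sph, fraction = 0.10) {
  stopifnot(inherits(cloud, "oriented_cloud"), inherits(sph, "sphere"),
            fraction >= 0, fraction < 1)
  n <- nrow(cloud$points)
  if (n == 0) stop("cannot prune an empty cloud")
  if (fraction == 0) return(cloud)
  k <- ceiling(fraction * n)
  d2 <- sphere_dist2(cloud$points, sph)
  drop <- order(-d2, seq_len(n))[seq_len(k)]
  subset_cloud(cloud, setdiff(seq_len(n), drop))
}

#' Iterative ILSS fit with normal filtering and distance pruning
#'
#' Alternates [fit_sphere_lsq()], [filter_by_normal()] and
#' [prune_farthest()] until the fitted radius changes by less than
#' `config$radius_tol` or `config$max_iterations` is reached, then applies
#' the geometric refinement to the retained points. Within the loop the
#' algebraic fit is used, so the recorded algebraic loss is non-increasing
#' across iterations.
#'
#' @param cloud an [oriented_cloud()].
#' @param config a [fit_config()].
#' @return A list with elements `sphere` (the final [sphere()]), `cloud`
#'   (retained points) and `diagnostics` (a tibble with per-iteration
#'   radius, point count and algebraic loss).
#' @export
iterate_fit <- function(cloud, config = fit_config()) {
  stopifnot(inherits(cloud, "oriented_cloud"), inherits(config, "fit_config"))
  cur <- cloud
  rows <- list()
  r_prev <- NA_real_
  sph <- NULL
  for (it in seq_len(config$max_iterations)) {
    if (nrow(cur$points) < 4) {
      stop("fewer than 4 points remain at iteration ", it,
           "; pruning configuration is too aggressive for this cloud")
    }
    sph <- fit_sphere_lsq(cur, refine = FALSE)
    rows[[it]] <- tibble::tibble(
      iteration = it,
      radius = sph$radius,
      n_points = nrow(cur$points),
      algebraic_loss = sphere_algebraic_loss(cur$points, sph))
    if (!is.na(r_prev) && abs(sph$radius - r_prev) < config$radius_tol) break
    r_prev <- sph$radius
    if (it == config$max_iterations) break
    cur <- filter_by_normal(cur, sph, config)
    if (config$prune) cur <- prune_farthest(cur, sph, config$prune_fraction)
  }
  final <- fit_sphere_lsq(cur, refine = TRUE)
  list(sphere = final, cloud = cur,
       diagnostics = do.call(rbind, rows))
}
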