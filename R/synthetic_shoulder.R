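# Parametric synthetic post-RSA shoulder. The generator emulates what the
# imaging protocol delivers after segmentation: a labeled volume and
# oriented point clouds for the deltoid, acromion, clavicle and humeral
# diaphysis, built around a spherical implant that the middle deltoid wraps
# like a string on a pulley. Because every landmark is known in closed
# form, each downstream stage (sphere fit, reslicing, angle measurement,
# CER, DMA) has an exact oracle.

# run code with a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

slice_site_map <- c(S1 = "P1", S2 = "M1", S3 = "A3", S4 = "A2")

#' Parameters of the synthetic post-RSA shoulder
#'
#' Defaults describe a right shoulder imaged at the nominal 80-degree
#' arm position, in world millimetres with X mediolateral (lateral
#' positive), Y parallel to the humeral diaphysis and Z completing a
#' right-handed (anterior-positive) frame. The default geometry was chosen
#' so that the slice angles at 0 mm lateralization fall in the ranges
#' observed clinically (T about 53-57 degrees, E about 7-9 degrees) and
#' respond monotonically to glenosphere lateralization.
#'
#' @param implant_center glenosphere centre (mm).
#' @param implant_radius glenosphere / ILSS radius (mm); clinical range is
#'   roughly 26-39 mm.
#' @param diaphysis_axis unit direction of the humeral diaphysis (the Y'Y
#'   axis); normalised internally.
#' @param diaphysis_radius humeral shaft radius (mm).
#' @param diaphysis_center Point 3: centre of the humeral diaphysis (mm).
#' @param distal_insertion DIP, the deltoid-V insertion on the humerus (mm).
#' @param acromial_center centre of the acromial reference sphere
#'   (Point-1 source).
#' @param acromial_radius radius of the acromial reference sphere (mm).
#' @param arc_height height of the acromial insertion arc above the
#'   acromial sphere centre (mm); the arc is the horizontal circle cut from
#'   the acromial sphere at that height.
#' @param insertion_angles named arc angles (degrees) of the four Sakoma
#'   insertion sites, strictly increasing in the order P1, M1, A3, A2.
#' @param arc_span angular span (degrees) of the acromial arc.
#' @param deltoid_thickness deltoid sheet thickness (mm), used only for
#'   voxelisation; the static model itself treats the muscle as massless
#'   and infinitely thin.
#' @param voxel_spacing voxel spacing (mm); the through-plane spacing
#'   defaults to the 3 mm acquisition slice thickness.
#' @param arm_angle angle (degrees) between the humeral diaphysis and the
#'   scapular plane; deviations from the nominal 80 rotate the humerus
#'   (axis, Point 3 and DIP) about the implant centre in the XY plane.
#' @param noise_sd standard deviation (mm) of segmentation jitter applied
#'   along point normals.
#' @param seed default RNG seed for [generate_shoulder()].
#' @return An object of class `shoulder_params`.
#' @export
shoulder_params <- function(implant_center = c(0, 0, 0),
                            implant_radius = 33,
                            diaphysis_axis = c(0, 1, 0),
                            diaphysis_radius = 12,
                            diaphysis_center = c(10, -60, 0),
                            distal_insertion = c(24, -78, -3),
                            acromial_center = c(-20, 21, 0),
                            acromial_radius = sqrt(12^2 + 18^2),
                            arc_height = 18,
                            insertion_angles = c(P1 = -50, M1 = -20,
                                                 A3 = 10, A2 = 40),
                            arc_span = c(-60, 50),
                            deltoid_thickness = 5,
                            voxel_spacing = c(1.5, 1.5, 3),
                            arm_angle = 80,
                            noise_sd = 0,
                            seed = 1L) {
  p <- list(implant_center = as.numeric(implant_center),
            implant_radius = as.numeric(implant_radius),
            diaphysis_axis = vunit(as.numeric(diaphysis_axis)),
            diaphysis_radius = as.numeric(diaphysis_radius),
            diaphysis_center = as.numeric(diaphysis_center),
            distal_insertion = as.numeric(distal_insertion),
            acromial_center = as.numeric(acromial_center),
            acromial_radius = as.numeric(acromial_radius),
            arc_height = as.numeric(arc_height),
            insertion_angles = insertion_angles,
            arc_span = as.numeric(arc_span),
            deltoid_thickness = as.numeric(deltoid_thickness),
            voxel_spacing = as.numeric(voxel_spacing),
            arm_angle = as.numeric(arm_angle),
            noise_sd = as.numeric(noise_sd),
            seed = as.integer(seed))
  class(p) <- "shoulder_params"
  validate_shoulder_params(p)
  p
}

validate_shoulder_params <- function(p) {
  if (p$implant_radius <= 0) stop("implant_radius must be positive")
  if (any(p$voxel_spacing <= 0)) stop("voxel spacings must be positive")
  if (p$diaphysis_radius <= 0) stop("diaphysis_radius must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (!identical(names(p$insertion_angles), c("P1", "M1", "A3", "A2"))) {
    stop("insertion_angles must be named P1, M1, A3, A2")
  }
  if (any(diff(p$insertion_angles) <= 0)) {
    stop("insertion sites must be distinct and ordered P1 -> M1 -> A3 -> A2",
         " along the acromial arc")
  }
  if (p$arc_height >= p$acromial_radius) {
    stop("arc_height must be smaller than acromial_radius")
  }
  if (any(p$insertion_angles < p$arc_span[1] |
            p$insertion_angles > p$arc_span[2])) {
    stop("insertion sites must lie within the acromial arc span")
  }
  g <- effective_geometry(p)
  if (vnorm(g$distal_insertion - p$implant_center) <= p$implant_radius) {
    stop("distal insertion point lies inside the implant sphere")
  }
  if (sum((g$distal_insertion - p$implant_center) * g$diaphysis_axis) >= 0) {
    stop("distal insertion point must be distal to the implant along the ",
         "diaphysis axis")
  }
  sites <- insertion_site_positions(p)
  inside <- sqrt(rowSums(sweep(sites, 2, p$implant_center)^2)) <=
    p$implant_radius
  if (any(inside)) {
    stop("insertion site(s) ", paste(rownames(sites)[inside], collapse = ", "),
         " lie inside the implant sphere")
  }
  invisible(p)
}

#' @export
print.shoulder_params <- function(x, ...) {
  cat(sprintf(paste0("<shoulder_params> implant r = %.2f mm at ",
                     "(%.1f, %.1f, %.1f), arm %.0f deg, noise %.2f mm\n"),
              x$implant_radius, x$implant_center[1], x$implant_center[2],
              x$implant_center[3], x$arm_angle, x$noise_sd))
  invisible(x)
}

# Humeral-side geometry after applying the arm-position rotation: the
# mapping from the 80-degree imaging position to relative DIP/implant
# positions is not observable from the images, so deviations from 80 are
# exposed as a rigid rotation of the humerus about the implant centre.
effective_geometry <- function(p) {
  delta <- deg2rad(-(p$arm_angle - 80))
  rot <- function(v) {
    rel <- v - p$implant_center
    p$implant_center + c(cos(delta) * rel[1] - sin(delta) * rel[2],
                         sin(delta) * rel[1] + cos(delta) * rel[2],
                         rel[3])
  }
  axis <- c(cos(delta) * p$diaphysis_axis[1] - sin(delta) * p$diaphysis_axis[2],
            sin(delta) * p$diaphysis_axis[1] + cos(delta) * p$diaphysis_axis[2],
            p$diaphysis_axis[3])
  list(diaphysis_axis = vunit(axis),
       diaphysis_center = rot(p$diaphysis_center),
       distal_insertion = rot(p$distal_insertion))
}

#' Acromial insertion arc
#'
#' The horizontal circle cut from the acromial reference sphere at
#' `arc_height` above its centre; insertion sites live on this arc.
#'
#' @param params a [shoulder_params()].
#' @return list with `center` (length-3 mm), `radius` (mm) and `span`
#'   (degrees), as consumed by [insertion_points()].
#' @export
acromial_arc <- function(params) {
  stopifnot(inherits(params, "shoulder_params"))
  list(center = params$acromial_center + c(0, params$arc_height, 0),
       radius = sqrt(params$acromial_radius^2 - params$arc_height^2),
       span = params$arc_span)
}

#' World positions of the four Sakoma insertion sites
#'
#' @param params a [shoulder_params()].
#' @return 4 x 3 matrix with rows P1, M1, A3, A2.
#' @export
insertion_site_positions <- function(params) {
  arc <- acromial_arc(params)
  th <- deg2rad(params$insertion_angles)
  pos <- cbind(arc$center[1] + arc$radius * cos(th),
               arc$center[2],
               arc$center[3] + arc$radius * sin(th))
  rownames(pos) <- names(params$insertion_angles)
  pos
}

# Frame of one anatomical slice: Point 1 = acromial sphere centre, Point 2
# = the slice's insertion site, Point 3 = diaphysis centre.
slice_frame <- function(params, slice, pixel_spacing = 0.5) {
  slice <- match.arg(slice, names(slice_site_map))
  g <- effective_geometry(params)
  site <- insertion_site_positions(params)[slice_site_map[[slice]], ]
  plane_from_three_points(params$acromial_center, site, g$diaphysis_center,
                          ydir = g$diaphysis_axis,
                          pixel_spacing = pixel_spacing)
}

# Full in-plane construction for one slice at one lateral offset of the
# (true or fitted) implant sphere.
slice_construction <- function(sph, frame, dip_world, pip_world) {
  circ <- slice_circle(sph, frame)
  tangent_construction(circ,
                       project_to_plane(frame, dip_world),
                       project_to_plane(frame, pip_world))
}

#' Closed-form slice angles for a synthetic shoulder
#'
#' Computes E, B and T for one slice directly from the generating
#' parameters (no fitting, no resampling): the implant sphere is cut by the
#' slice plane, the DIP and the slice's insertion site are projected into
#' the plane, and the two external tangent lines are constructed. This is
#' the ground-truth oracle for the measurement pipeline.
#'
#' @param params a [shoulder_params()].
#' @param slice one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param offset lateral (world +X) glenosphere offset in mm.
#' @return an [angle_set()] with the `tangent_construction` attached as
#'   attribute `construction`.
#' @export
analytic_angles <- function(params, slice, offset = 0) {
  stopifnot(inherits(params, "shoulder_params"))
  g <- effective_geometry(params)
  frame <- slice_frame(params, slice)
  sph <- lateralize(sphere(params$implant_center, params$implant_radius),
                    offset)
  site <- insertion_site_positions(params)[slice_site_map[[match.arg(
    slice, names(slice_site_map))]], ]
  tc <- slice_construction(sph, frame, g$distal_insertion, site)
  ang <- measure_angles(tc)
  attr(ang, "construction") <- tc
  ang
}

# Ground-truth table across slices and offsets.
ground_truth_table <- function(params, offsets = c(0, 6, 9, 12)) {
  rows <- list()
  for (slice in names(slice_site_map)) {
    for (off in offsets) {
      ang <- analytic_angles(params, slice, off)
      tc <- attr(ang, "construction")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slice = slice, offset = off,
        E = ang$E, B = ang$B, T = ang$T,
        rho = tc$circle$radius,
        cer = cer(ang),
        dma_md_line = dma(tc, variant = "perpendicular_to_F1_line"),
        dma_perpendicular = dma(tc, variant = "paper_perpendicular_line"))
    }
  }
  do.call(rbind, rows)
}

# ---- deltoid fiber paths --------------------------------------------------

# Taut string from the DIP to an acromial point q around the implant
# sphere, computed in the wrap plane through the sphere centre. Returns 3D
# sample points with inward (towards the implant centre side) unit normals
# and a flag for on-sphere contact points.
fiber_path <- function(params, q, n_arc = 14, n_seg = 2) {
  g <- effective_geometry(params)
  cen <- params$implant_center
  r <- params$implant_radius
  dip <- g$distal_insertion
  nrm <- cross3(q - cen, dip - cen)
  e1 <- vunit(dip - cen)
  e2 <- vunit(cross3(vunit(nrm), e1))
  to2 <- function(p) c(sum((p - cen) * e1), sum((p - cen) * e2))
  to3 <- function(xy) cen + xy[1] * e1 + xy[2] * e2
  circ <- circle2d(c(0, 0), r)
  d2 <- to2(dip)
  q2 <- to2(q)
  best <- NULL
  for (sides in list(c("left", "right"), c("right", "left"))) {
    md <- try(tangent_from_point(d2, circ, sides[1]), silent = TRUE)
    px <- try(tangent_from_point(q2, circ, sides[2]), silent = TRUE)
    if (inherits(md, "try-error") || inherits(px, "try-error")) next
    a1 <- attr(md, "contact"); a2 <- attr(px, "contact")
    ph1 <- atan2(a1[2], a1[1]); ph2 <- atan2(a2[2], a2[1])
    ccw <- sides[1] == "left"
    dphi <- if (ccw) (ph2 - ph1) %% (2 * pi) else (ph1 - ph2) %% (2 * pi)
    len <- vnorm(a1 - d2) + r * dphi + vnorm(q2 - a2)
    if (is.null(best) || len < best$len) {
      best <- list(len = len, a1 = a1, a2 = a2, ph1 = ph1,
                   dphi = if (ccw) dphi else -dphi)
    }
  }
  if (is.null(best)) stop("no taut fiber path exists for this geometry")
  phis <- best$ph1 + seq(0, best$dphi, length.out = n_arc)
  arc2 <- cbind(r * cos(phis), r * sin(phis))
  seg_t <- seq_len(n_seg) / (n_seg + 1)
  seg1 <- outer(1 - seg_t, d2) + outer(seg_t, best$a1)
  seg2 <- outer(1 - seg_t, best$a2) + outer(seg_t, q2)
  pts2 <- rbind(seg1, arc2, seg2)
  contact <- c(rep(FALSE, n_seg), rep(TRUE, n_arc), rep(FALSE, n_seg))
  pts3 <- t(apply(pts2, 1, to3))
  # inward normals: on the arc, exactly towards the centre; on the straight
  # segments, the in-plane perpendicular of the fiber on the implant side
  normals <- matrix(0, nrow(pts2), 3)
  for (i in seq_len(nrow(pts2))) {
    if (contact[i]) {
      normals[i, ] <- vunit(cen - pts3[i, ])
    } else {
      dir2 <- if (i <= n_seg) best$a1 - d2 else q2 - best$a2
      perp <- c(-dir2[2], dir2[1])
      if (sum(perp * (-pts2[i, ])) < 0) perp <- -perp
      perp <- vunit(perp)
      normals[i, ] <- vunit(perp[1] * e1 + perp[2] * e2)
    }
  }
  list(points = pts3, normals = normals, contact = contact)
}

deltoid_cloud <- function(params, n_fibers = 36, n_arc = 14, n_seg = 2) {
  span <- params$arc_span
  th <- seq(span[1], span[2], length.out = n_fibers)
  arc <- acromial_arc(params)
  pts <- list(); nrm <- list(); contact <- list()
  for (i in seq_along(th)) {
    q <- c(arc$center[1] + arc$radius * cos(deg2rad(th[i])),
           arc$center[2],
           arc$center[3] + arc$radius * sin(deg2rad(th[i])))
    fp <- fiber_path(params, q, n_arc = n_arc, n_seg = n_seg)
    pts[[i]] <- fp$points; nrm[[i]] <- fp$normals; contact[[i]] <- fp$contact
  }
  cl <- oriented_cloud(do.call(rbind, pts), do.call(rbind, nrm), "deltoid")
  attr(cl, "contact") <- unlist(contact)
  cl
}

acromion_cloud <- function(params, n_theta = 30, n_psi = 8) {
  A <- params$acromial_center; Ra <- params$acromial_radius
  psi0 <- asin(params$arc_height / Ra)
  th <- deg2rad(seq(params$arc_span[1], params$arc_span[2],
                    length.out = n_theta))
  psi <- seq(psi0 - 0.25, psi0 + 0.3, length.out = n_psi)
  g <- expand.grid(th = th, psi = psi)
  pts <- cbind(A[1] + Ra * cos(g$psi) * cos(g$th),
               A[2] + Ra * sin(g$psi),
               A[3] + Ra * cos(g$psi) * sin(g$th))
  oriented_cloud(pts, sweep(pts, 2, A) / Ra, "acromion")
}

diaphysis_cloud <- function(params, n_h = 20, n_phi = 18,
                            extent = c(-50, 25)) {
  g <- effective_geometry(params)
  a <- g$diaphysis_axis
  u <- vunit(cross3(a, c(0, 0, 1)))
  w <- cross3(a, u)
  grid <- expand.grid(t = seq(extent[1], extent[2], length.out = n_h),
                      phi = seq(0, 2 * pi, length.out = n_phi + 1)[-1])
  radial <- outer(cos(grid$phi), u) + outer(sin(grid$phi), w)
  pts <- sweep(outer(grid$t, a) + params$diaphysis_radius * radial,
               2, g$diaphysis_center, "+")
  oriented_cloud(pts, radial, "diaphysis")
}

# ---- labeled volume -------------------------------------------------------

#' Labeled segmentation volume
#'
#' 3D integer label grid with codes 0 = background, 1 = deltoid,
#' 2 = acromion, 3 = clavicle, 4 = humeral diaphysis. World coordinates
#' follow `world = origin + spacing * index` with 0-based indices (a
#' diagonal voxel-to-world affine).
#'
#' @param voxels 3D integer array of label codes.
#' @param spacing length-3 positive voxel spacing (mm).
#' @param origin world coordinate (mm) of the voxel with index (0,0,0).
#' @return An object of class `labeled_volume` with an `affine` field
#'   (4 x 4 voxel-to-world transform).
#' @export
labeled_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3,
            length(origin) == 3)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  vals <- unique(as.integer(voxels))
  if (!all(vals %in% 0:4)) {
    stop("labels must be restricted to codes 0 (bg), 1 (deltoid), ",
         "2 (acromion), 3 (clavicle), 4 (diaphysis)")
  }
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), affine = aff),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(factor(as.integer(x$voxels), levels = 0:4,
                      labels = c("bg", "deltoid", "acromion", "clavicle",
                                 "diaphysis")))
  print(tab)
  invisible(x)
}

voxel_centers <- function(dims, spacing, origin) {
  list(x = origin[1] + spacing[1] * (seq_len(dims[1]) - 1),
       y = origin[2] + spacing[2] * (seq_len(dims[2]) - 1),
       z = origin[3] + spacing[3] * (seq_len(dims[3]) - 1))
}

rasterize_shoulder <- function(params, bounds = rbind(c(-52, 52),
                                                      c(-112, 62),
                                                      c(-48, 48))) {
  sp <- params$voxel_spacing
  origin <- bounds[, 1]
  dims <- floor((bounds[, 2] - bounds[, 1]) / sp) + 1
  cc <- voxel_centers(dims, sp, origin)
  X <- array(rep(cc$x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cc$y, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cc$z, each = dims[1] * dims[2]), dims)
  lab <- array(0L, dims)

  # deltoid sheet: stamp balls of radius thickness/2 along the fiber
  # mid-surface (paths offset outwards by thickness/2 so the internal
  # aspect stays tangent to the implant sphere)
  th2 <- params$deltoid_thickness / 2
  dens <- deltoid_cloud(params, n_fibers = 48, n_arc = 26, n_seg = 8)
  mid <- dens$points - th2 * dens$normals
  for (i in seq_len(nrow(mid))) {
    p <- mid[i, ]
    lo <- pmax(ceiling((p - th2 - origin) / sp), 0)
    hi <- pmin(floor((p + th2 - origin) / sp), dims - 1)
    if (any(hi < lo)) next
    gx <- origin[1] + sp[1] * (lo[1]:hi[1])
    gy <- origin[2] + sp[2] * (lo[2]:hi[2])
    gz <- origin[3] + sp[3] * (lo[3]:hi[3])
    g <- expand.grid(x = gx, y = gy, z = gz)
    ok <- (g$x - p[1])^2 + (g$y - p[2])^2 + (g$z - p[3])^2 <= th2^2
    if (!any(ok)) next
    gi <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])[ok, ]
    lab[cbind(gi$i + 1, gi$j + 1, gi$k + 1)] <- 1L
  }

  # acromion: spherical shell patch around the insertion arc
  A <- params$acromial_center; Ra <- params$acromial_radius
  dist_a <- sqrt((X - A[1])^2 + (Y - A[2])^2 + (Z - A[3])^2)
  psi <- asin(pmin(1, pmax(-1, (Y - A[2]) / pmax(dist_a, 1e-9))))
  psi0 <- asin(params$arc_height / Ra)
  theta <- rad2deg(atan2(Z - A[3], X - A[1]))
  acr <- abs(dist_a - Ra) <= 3.5 & psi >= psi0 - 0.3 & psi <= psi0 + 0.35 &
    theta >= params$arc_span[1] - 15 & theta <= params$arc_span[2] + 15
  lab[acr] <- 2L

  # clavicle: medial tube running towards the acromion (cosmetic)
  arcc <- acromial_arc(params)
  clav <- (Y - arcc$center[2])^2 + (Z - 12)^2 <= 5^2 &
    X >= bounds[1, 1] & X <= A[1] + 5
  lab[clav] <- 3L

  # humeral diaphysis: cylinder about the (arm-rotated) axis
  g <- effective_geometry(params)
  vx <- X - g$diaphysis_center[1]
  vy <- Y - g$diaphysis_center[2]
  vz <- Z - g$diaphysis_center[3]
  t_ax <- vx * g$diaphysis_axis[1] + vy * g$diaphysis_axis[2] +
    vz * g$diaphysis_axis[3]
  d2_ax <- vx^2 + vy^2 + vz^2 - t_ax^2
  dia <- d2_ax <= params$diaphysis_radius^2 & t_ax >= -50 & t_ax <= 25
  lab[dia] <- 4L

  labeled_volume(lab, sp, origin)
}

#' Generate a synthetic post-RSA shoulder
#'
#' Produces the labeled volume, per-structure oriented point clouds and the
#' closed-form ground truth (implant sphere; per-slice, per-offset angles,
#' CER and DMA). With `noise_sd = 0` the deltoid contact points lie exactly
#' on the implant sphere; with noise, points are jittered along their
#' normals. Identical `(params, seed)` reproduce identical output.
#'
#' @param params a [shoulder_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @param offsets lateral offsets (mm) tabulated in the ground truth.
#' @param with_volume logical; rasterise the labeled volume (slower than
#'   the clouds alone).
#' @param n_fibers number of deltoid fibers sampled across the acromial
#'   arc for the point cloud.
#' @return A list with elements `params`, `clouds` (named list of
#'   [oriented_cloud()]s), `ground_truth` (list with `sphere` and the
#'   `per_slice` tibble) and `volume` (a [labeled_volume()] or `NULL`).
#' @export
generate_shoulder <- function(params, seed = params$seed,
                              offsets = c(0, 6, 9, 12),
                              with_volume = TRUE, n_fibers = 36) {
  stopifnot(inherits(params, "shoulder_params"))
  with_seed(seed, {
    clouds <- list(deltoid = deltoid_cloud(params, n_fibers = n_fibers),
                   acromion = acromion_cloud(params),
                   diaphysis = diaphysis_cloud(params))
    if (params$noise_sd > 0) {
      for (nm in names(clouds)) {
        cl <- clouds[[nm]]
        jit <- stats::rnorm(nrow(cl$points), 0, params$noise_sd)
        cl$points <- cl$points + jit * cl$normals
        clouds[[nm]] <- cl
      }
    }
    gt <- list(sphere = sphere(params$implant_center, params$implant_radius),
               per_slice = ground_truth_table(params, offsets))
    vol <- if (with_volume) rasterize_shoulder(params) else NULL
    list(params = params, clouds = clouds, ground_truth = gt, volume = vol)
  })
}

#' Simulate a repeat segmentation of a labeled volume
#'
#' Applies a smooth random displacement field (coarse white noise,
#' trilinearly upsampled, so errors are spatially correlated as real
#' segmentation errors are) of amplitude `noise_sd` mm to the label map,
#' emulating a second rater or a repeat session.
#'
#' @param volume a [labeled_volume()].
#' @param noise_sd displacement-field standard deviation in mm; `0`
#'   returns the input unchanged.
#' @param seed RNG seed.
#' @param coarse_step coarse-grid step (voxels) of the underlying noise.
#' @return a [labeled_volume()].
#' @export
perturb_segmentation <- function(volume, noise_sd, seed = 1L,
                                 coarse_step = 6) {
  stopifnot(inherits(volume, "labeled_volume"), noise_sd >= 0)
  if (noise_sd == 0) return(volume)
  dims <- dim(volume$voxels)
  with_seed(seed, {
    cdims <- pmax(ceiling((dims - 1) / coarse_step) + 2, 2)
    disp <- lapply(1:3, function(a) {
      coarse <- array(stats::rnorm(prod(cdims)), cdims)
      up <- upsample_trilinear(coarse, dims, coarse_step)
      up / stats::sd(up) * noise_sd
    })
    # pull-back warp, nearest-neighbour labels
    idx <- lapply(1:3, function(a) {
      base <- switch(a,
                     rep(seq_len(dims[1]), times = dims[2] * dims[3]),
                     rep(rep(seq_len(dims[2]), each = dims[1]),
                         times = dims[3]),
                     rep(seq_len(dims[3]), each = dims[1] * dims[2]))
      src <- round(base + as.numeric(disp[[a]]) / volume$spacing[a])
      pmin(pmax(src, 1), dims[a])
    })
    lin <- idx[[1]] + dims[1] * (idx[[2]] - 1) +
      dims[1] * dims[2] * (idx[[3]] - 1)
    labeled_volume(array(volume$voxels[lin], dims), volume$spacing,
                   volume$origin)
  })
}

upsample_trilinear <- function(coarse, dims, step) {
  cd <- dim(coarse)
  pos <- lapply(1:3, function(a) pmin((seq_len(dims[a]) - 1) / step + 1,
                                      cd[a] - 1e-9))
  i0 <- lapply(pos, floor)
  fr <- lapply(1:3, function(a) pos[[a]] - i0[[a]])
  ex <- function(v, a) switch(a,
                              rep(v, times = dims[2] * dims[3]),
                              rep(rep(v, each = dims[1]), times = dims[3]),
                              rep(v, each = dims[1] * dims[2]))
  out <- numeric(prod(dims))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- ex(if (dx) fr[[1]] else 1 - fr[[1]], 1) *
      ex(if (dy) fr[[2]] else 1 - fr[[2]], 2) *
      ex(if (dz) fr[[3]] else 1 - fr[[3]], 3)
    lin <- ex(pmin(i0[[1]] + dx, cd[1]), 1) +
      cd[1] * (ex(pmin(i0[[2]] + dy, cd[2]), 2) - 1) +
      cd[1] * cd[2] * (ex(pmin(i0[[3]] + dz, cd[3]), 3) - 1)
    out <- out + w * coarse[lin]
  }
  array(out, dims)
}

#' Extract the internal-aspect surface of a labeled structure
#'
#' Collects the voxel faces of `label` voxels whose neighbour is background
#' and which face towards `toward` (typically the implant centre), giving
#' the oriented point cloud an operator would pick on the internal aspect
#' of the muscle. Normals point towards `toward`'s side (the inward
#' convention).
#'
#' @param volume a [labeled_volume()].
#' @param label integer label code (default 1, deltoid).
#' @param toward length-3 world point the surface must face.
#' @param max_distance optional radius (mm) around `toward`; faces farther
#'   away are discarded, mimicking an operator picking points only near
#'   the implant bulge.
#' @return an [oriented_cloud()].
#' @export
extract_internal_surface <- function(volume, label = 1L, toward,
                                     max_distance = NULL) {
  stopifnot(inherits(volume, "labeled_volume"), length(toward) == 3)
  vox <- volume$voxels
  dims <- dim(vox)
  pts <- list(); nrm <- list()
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nb <- shift_array(vox, d, fill = 0L)
    face <- which(vox == label & nb == 0L, arr.ind = TRUE)
    if (nrow(face) == 0) next
    centers <- sweep(sweep(face - 1, 2, volume$spacing, "*"), 2,
                     volume$origin, "+")
    fpts <- centers + matrix(d * volume$spacing / 2, nrow(face), 3,
                             byrow = TRUE)
    facing <- rowSums(sweep(-fpts, 2, -as.numeric(toward)) *
                        matrix(d, nrow(face), 3, byrow = TRUE)) > 0
    if (!is.null(max_distance)) {
      facing <- facing &
        sqrt(rowSums(sweep(fpts, 2, as.numeric(toward))^2)) <= max_distance
    }
    if (!any(facing)) next
    pts[[length(pts) + 1L]] <- fpts[facing, , drop = FALSE]
    nrm[[length(nrm) + 1L]] <- matrix(vunit(d), sum(facing), 3, byrow = TRUE)
  }
  if (length(pts) == 0) stop("no internal-aspect faces found for label ",
                             label)
  oriented_cloud(do.call(rbind, pts), do.call(rbind, nrm),
                 label = paste0("label", label, "_internal"))
}

# neighbour lookup: value of the voxel at index + d, 0 outside
shift_array <- function(a, d, fill = 0L) {
  dims <- dim(a)
  out <- array(fill, dims)
  src <- lapply(1:3, function(i) {
    s <- seq_len(dims[i]) + d[i]
    s[s >= 1 & s <= dims[i]]
  })
  dst <- lapply(1:3, function(i) src[[i]] - d[i])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Synthetic patient cohort
#'
#' Builds one [shoulder_params()] per implant radius, with small seeded
#' anatomical jitter (insertion positions, acromion, humerus) so patients
#' differ in more than the implant size.
#'
#' @param radii implant radii in mm; defaults to the seven published ILSS
#'   radii, see [reference_ilss_radii()].
#' @param seed RNG seed for the anatomical jitter.
#' @param jitter logical; disable for identical anatomy across patients.
#' @return list of [shoulder_params()], one per patient.
#' @export
synthetic_cohort <- function(radii = reference_ilss_radii(), seed = 1L,
                             jitter = TRUE) {
  with_seed(seed, {
    lapply(seq_along(radii), function(i) {
      base <- shoulder_params(implant_radius = radii[i], seed = seed + i)
      if (!jitter) return(base)
      shoulder_params(
        implant_radius = radii[i],
        distal_insertion = base$distal_insertion + stats::rnorm(3, 0, 1.5),
        acromial_center = base$acromial_center + stats::rnorm(3, 0, 1.0),
        diaphysis_center = base$diaphysis_center +
          c(stats::rnorm(1, 0, 1.0), 0, 0),
        insertion_angles = base$insertion_angles +
          c(P1 = 0, M1 = 0, A3 = 0, A2 = 0) + stats::rnorm(4, 0, 2.5),
        seed = seed + i)
    })
  })
}
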