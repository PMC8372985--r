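# Static string-on-pulley model of the middle deltoid. With fiber tension
# F1 = F2, the axial (Y'Y) reaction of the muscle on the pulley is
# R'y = -2 F1 cos(T) cos(T+E) and the axial elevating component at the
# distal insertion is F'1y = F1 cos(E); their ratio is the
# coaptation/elevation ratio (CER), reported as a positive magnitude.

#' Coaptation/Elevation Ratio
#'
#' `CER = | -2 cos(T) cos(T+E) / cos(E) |`, evaluated from angles in
#' degrees. The derivation carries a minus sign (the coapting component
#' opposes the elevating one); the ratio is reported as a positive
#' magnitude, matching how study tables print it.
#'
#' @param T half of the pulley deflection angle B, in degrees; or an
#'   [angle_set()] (in which case `E` is taken from it).
#' @param E angle between the MD line and the diaphysis axis, degrees.
#' @return numeric CER magnitude (vectorised over `T`, `E`).
#' @export
cer <- function(T, E = NULL) {
  if (inherits(T, "angle_set")) {
    E <- T$E
    T <- T$T
  }
  stopifnot(is.numeric(T), is.numeric(E))
  if (any(E >= 90) || any(E < 0)) {
    stop("angle E must lie in [0, 90) degrees (cos(E) must be positive)")
  }
  if (any(T <= 0) || any(T >= 90)) {
    stop("angle T must lie in (0, 90) degrees")
  }
  abs(-2 * cos(deg2rad(T)) * cos(deg2rad(T + E)) / cos(deg2rad(E)))
}

#' Force system of the static deltoid model
#'
#' Builds the 2D force system in slice coordinates (x lateral, y along the
#' diaphysis axis) for fiber tension `F1` (= `F2`, the string assumption)
#' and a measured [angle_set()]. The distal fiber direction makes angle E
#' with +y and the proximal fiber direction makes angle `B + E = 2T + E`.
#'
#' @param F1 positive fiber tension (arbitrary units; the CER is a ratio).
#' @param angles an [angle_set()].
#' @return An object of class `force_system`: the insertion forces
#'   `F1_vec`, `F2_vec`, the pulley reaction on the muscle `R_vec`, the
#'   action of the muscle on the pulley `Rprime_vec = -R_vec`, the distal
#'   action on the humerus `F1prime_vec = -F1_vec`, their axial components
#'   `Ry`, `Rprime_y`, `F1prime_y`, and the equilibrium `residual`.
#' @export
force_components <- function(F1, angles) {
  stopifnot(inherits(angles, "angle_set"))
  if (!is.numeric(F1) || F1 <= 0) stop("fiber tension F1 must be positive")
  E <- deg2rad(angles$E)
  B <- deg2rad(angles$B)
  d1 <- c(sin(E), cos(E))          # distal insertion -> pulley
  d2 <- c(sin(E + B), cos(E + B))  # proximal insertion -> pulley
  F1_vec <- -F1 * d1               # pull on the muscle towards the DIP
  F2_vec <- -F1 * d2               # pull on the muscle towards the PIP
  R_vec <- -(F1_vec + F2_vec)      # pulley reaction on the muscle
  Tm <- deg2rad(angles$T)
  structure(list(
    F1 = F1, F2 = F1,
    F1_vec = F1_vec, F2_vec = F2_vec, R_vec = R_vec,
    Rprime_vec = -R_vec, F1prime_vec = -F1_vec,
    Ry = F1 * (cos(E) + cos(2 * Tm + E)),
    Ry_product_form = 2 * F1 * cos(Tm) * cos(Tm + E),
    Rprime_y = -2 * F1 * cos(Tm) * cos(Tm + E),
    F1prime_y = F1 * cos(E),
    residual = vnorm(F1_vec + F2_vec + R_vec)),
    class = "force_system")
}

#' @export
print.force_system <- function(x, ...) {
  cat(sprintf("<force_system> F1 = %.3g, R'y = %.4f, F'1y = %.4f, CER = %.4f\n",
              x$F1, x$Rprime_y, x$F1prime_y, abs(x$Rprime_y / x$F1prime_y)))
  invisible(x)
}

#' Simulated glenosphere lateralization
#'
#' Translates the (fitted) implant sphere along the lateral world axis,
#' leaving its radius unchanged (the simplifying hypothesis of the
#' simulation: lateralization does not significantly modify the ILSS
#' radius).
#'
#' @param sph a [sphere()].
#' @param offset lateral offset in mm (>= 0).
#' @param axis world lateral direction (default +X).
#' @return the translated [sphere()].
#' @export
lateralize <- function(sph, offset, axis = c(1, 0, 0)) {
  stopifnot(inherits(sph, "sphere"))
  if (offset < 0) stop("lateral offset must be non-negative")
  sphere(sph$center + offset * vunit(axis), sph$radius)
}

#' Deltoid moment arm on a slice
#'
#' Two readings of the moment arm are implemented. The default,
#' `"perpendicular_to_F1_line"`, is the classical muscle moment arm: the
#' perpendicular distance from the joint centre (the in-plane implant
#' circle centre) to the MD line of action - for a tangent MD line this
#' equals the in-plane pulley radius. `"paper_perpendicular_line"` takes
#' the distance from the circle centre to the line through the DIP
#' perpendicular to the F1 direction.
#'
#' @param construction a [tangent_construction()].
#' @param variant which reading to compute.
#' @return moment arm in mm.
#' @export
dma <- function(construction,
                variant = c("perpendicular_to_F1_line",
                            "paper_perpendicular_line")) {
  stopifnot(inherits(construction, "tangent_construction"))
  variant <- match.arg(variant)
  cc <- construction$circle$center
  if (variant == "perpendicular_to_F1_line") {
    point_line_distance(cc, construction$md_line)
  } else {
    d1 <- construction$md_line$direction
    perp <- line2d(construction$dip2d, c(-d1[2], d1[1]))
    point_line_distance(cc, perp)
  }
}

#' Run the full measurement pipeline on synthetic patients
#'
#' For each patient: generate the oriented clouds, fit the ILSS to the
#' deltoid internal aspect (iterative normal-filter / prune / refit loop)
#' and the acromial reference sphere to the acromion cloud, then for each
#' slice and lateral offset build the slice plane from the three landmark
#' points, intersect the (lateralized) ILSS with it, construct the tangent
#' lines and record angles, CER and DMA.
#'
#' @param patients a [shoulder_params()] or list of them (see
#'   [synthetic_cohort()]).
#' @param offsets lateral offsets in mm (default `c(0, 6, 9, 12)`).
#' @param slices slice labels (default `S1`-`S4`).
#' @param config [fit_config()] for the ILSS fit.
#' @param seed base RNG seed; patient `i` uses `seed + i`.
#' @param translate_humerus logical; if `TRUE` the humerus (DIP and
#'   diaphysis) co-translates with the glenosphere, the situation in which
#'   lateralizing hardware preserves the moment arm. Default `FALSE`: only
#'   the implant sphere is translated, as in the core simulation.
#' @return tibble with one row per (patient, slice, offset): `E`, `B`, `T`
#'   (degrees), `rho` (in-plane pulley radius, mm), `cer`, `dma` (classical
#'   variant, mm), `dma_perpendicular` (mm) and the fitted ILSS radius.
#' @export
run_pipeline <- function(patients, offsets = c(0, 6, 9, 12),
                         slices = c("S1", "S2", "S3", "S4"),
                         config = fit_config(), seed = 1L,
                         translate_humerus = FALSE) {
  if (inherits(patients, "shoulder_params")) patients <- list(patients)
  rows <- list()
  for (i in seq_along(patients)) {
    params <- patients[[i]]
    gen <- generate_shoulder(params, seed = seed + i, with_volume = FALSE)
    ilss <- iterate_fit(gen$clouds$deltoid, config)$sphere
    acro <- fit_sphere_lsq(gen$clouds$acromion)
    g <- effective_geometry(params)
    sites <- insertion_site_positions(params)
    for (slice in slices) {
      site <- sites[slice_site_map[[slice]], ]
      frame <- tryCatch(
        plane_from_three_points(acro$center, site, g$diaphysis_center,
                                ydir = g$diaphysis_axis),
        error = function(e) stop("patient ", i, ", slice ", slice, ": ",
                                 conditionMessage(e)))
      for (off in offsets) {
        res <- tryCatch({
          sph_o <- lateralize(ilss, off)
          shift <- if (translate_humerus) c(off, 0, 0) else c(0, 0, 0)
          tc <- slice_construction(sph_o, frame,
                                   g$distal_insertion + shift, site)
          ang <- measure_angles(tc)
          tibble::tibble(
            patient = i, slice = slice, offset = off,
            E = ang$E, B = ang$B, T = ang$T,
            rho = tc$circle$radius,
            cer = cer(ang),
            dma = dma(tc, "perpendicular_to_F1_line"),
            dma_perpendicular = dma(tc, "paper_perpendicular_line"),
            ilss_radius = ilss$radius)
        }, error = function(e) {
          stop("patient ", i, ", slice ", slice, ", offset ", off, " mm: ",
               conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  do.call(rbind, rows)
}
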