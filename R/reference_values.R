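# Published reference values from the clinical MRI study of glenosphere
# lateralization that this model implements. These are printed inputs
# (implant sphere radii and mean slice angles), used to parameterise the
# synthetic cohort and to check the CER formula against the published
# ratio tables.

#' Published ILSS radii of the seven analysed patients
#'
#' @return named numeric vector of implant least-squares-sphere radii (mm),
#'   one per patient; their mean is 32.89 mm.
#' @export
reference_ilss_radii <- function() {
  c(P1 = 31.25, P3 = 36.30, P4 = 33.64, P5 = 25.72,
    P6 = 39.42, P7 = 32.16, P8 = 31.75)
}

#' Published mean slice angles and CER per lateralization condition
#'
#' Mean measured angles T and E (degrees) and the mean CER for each slice
#' (S1-S4) and lateral offset (0, 6, 9, 12 mm), as printed in the source
#' study's biomechanical-parameters table.
#'
#' @return tibble with columns `slice`, `offset`, `T_deg`, `E_deg`,
#'   `cer_printed`.
#' @export
reference_slice_angles <- function() {
  tibble::tibble(
    slice = rep(c("S1", "S2", "S3", "S4"), each = 4),
    offset = rep(c(0, 6, 9, 12), times = 4),
    T_deg = c(55.40, 42.71, 41.40, 38.75,
              55.43, 42.86, 41.75, 40.20,
              54.36, 44.79, 43.71, 40.60,
              54.14, 44.00, 42.50, 40.71),
    E_deg = c(9.14, 13.43, 15.14, 16.86,
              6.71, 11.57, 13.14, 14.86,
              7.29, 12.29, 13.71, 14.57,
              7.43, 13.00, 14.71, 16.00),
    cer_printed = c(0.49, 0.82, 0.84, 0.90,
                    0.53, 0.87, 0.88, 0.91,
                    0.55, 0.79, 0.79, 0.84,
                    0.56, 0.79, 0.80, 0.86))
}

#' Published all-slice mean CER per lateralization condition
#'
#' The study-level mean CER across all slices at 0, 6, 9 and 12 mm of
#' lateralization, as printed in the source study's results text.
#'
#' @return named numeric vector.
#' @export
reference_overall_cer <- function() {
  c(`0` = 0.54, `6` = 0.81, `9` = 0.83, `12` = 0.88)
}
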