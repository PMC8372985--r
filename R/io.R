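# Interchange: labeled volumes as NIfTI, spheres / parameters / ground
# truth as JSON, oriented point clouds as CSV.

#' Write a labeled volume as NIfTI
#'
#' @param volume a [labeled_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_labeled_volume <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(array(as.integer(volume$voxels),
                               dim(volume$voxels)))
  aff <- volume$affine
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labeled volume from NIfTI
#'
#' @param path a NIfTI file written by [write_labeled_volume()].
#' @return a [labeled_volume()].
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  labeled_volume(array(as.integer(img), dim(img)),
                 spacing = abs(diag(aff)[1:3]),
                 origin = aff[1:3, 4])
}

#' Write a sphere as JSON
#'
#' @param sph a [sphere()].
#' @param path output `.json` file.
#' @return invisibly, `path`.
#' @export
write_sphere_json <- function(sph, path) {
  stopifnot(inherits(sph, "sphere"))
  jsonlite::write_json(list(cent = sph$center, r = sph$radius), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sphere from JSON
#'
#' @param path file written by [write_sphere_json()].
#' @return a [sphere()].
#' @export
read_sphere_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sphere(x$cent, x$r)
}

#' Write the synthetic ground truth as JSON
#'
#' @param gen output of [generate_shoulder()].
#' @param path output `.json` file.
#' @return invisibly, `path`.
#' @export
write_ground_truth_json <- function(gen, path) {
  gt <- gen$ground_truth
  jsonlite::write_json(
    list(sphere = list(cent = gt$sphere$center, r = gt$sphere$radius),
         per_slice = gt$per_slice),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write / read an oriented point cloud as CSV
#'
#' Columns `x`, `y`, `z` and (if normals are present) `nx`, `ny`, `nz`.
#'
#' @param cloud an [oriented_cloud()].
#' @param path a `.csv` file.
#' @return invisibly `path`, or the [oriented_cloud()] for the reader.
#' @export
write_cloud_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "oriented_cloud"))
  df <- as.data.frame(cloud$points)
  names(df) <- c("x", "y", "z")
  if (!is.null(cloud$normals)) {
    nn <- as.data.frame(cloud$normals)
    names(nn) <- c("nx", "ny", "nz")
    df <- cbind(df, nn)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @param label structure tag for the cloud read back.
#' @export
read_cloud_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  normals <- if (all(c("nx", "ny", "nz") %in% names(df))) {
    as.matrix(df[, c("nx", "ny", "nz")])
  } else NULL
  oriented_cloud(as.matrix(df[, c("x", "y", "z")]), normals, label)
}
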