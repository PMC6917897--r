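# A term map is a 3D grid of association z scores plus a voxel->mm affine,
# the volumetric counterpart of a meta-analytic functional-association map.

#' Construct a term map
#'
#' A term map couples a 3D array of association z scores with a 4x4 affine
#' matrix mapping 0-based voxel indices (i, j, k, 1) to millimetre
#' coordinates, the NIfTI convention. All spatial operations in the package
#' go through the affine, so anisotropic or rotated grids are supported even
#' though the built-in simulator only emits diagonal affines.
#'
#' @param values 3D numeric array of z scores.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to mm.
#' @return object of class `term_map`.
#' @export
term_map <- function(values, affine) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (any(!is.finite(values))) stop("term map values must be finite")
  structure(list(values = values, affine = affine), class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "term_map: %d x %d x %d voxels, %d positive z, range [%.3g, %.3g]\n",
    d[1], d[2], d[3], sum(x$values > 0), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Millimetre coordinates of all voxel centers
#'
#' @param map a `term_map`.
#' @return matrix with one row per voxel (column-major order over the
#'   array) and columns x, y, z in mm.
#' @export
voxel_centers <- function(map) {
  d <- dim(map$values)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])))
  ijk1 <- cbind(idx - 1, 1)
  mm <- ijk1 %*% t(map$affine)
  colnames(mm) <- c("x", "y", "z", "w")
  mm[, 1:3, drop = FALSE]
}

#' Write a term map to NIfTI
#'
#' @param map a `term_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_term_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a term map from NIfTI
#'
#' @param path NIfTI file with a float z-score volume.
#' @return a `term_map`.
#' @export
read_term_map <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL)
  term_map(array(as.numeric(img), dim = dim(img)), matrix(aff, 4, 4))
}
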