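# Pair each expression sample with a term-map z score: snap mm coordinates
# to voxels through the affine, keep samples in strictly positive-z voxels,
# and smooth expression over a spherical sample neighborhood.

#' Map millimetre coordinates to voxel indices
#'
#' Applies the inverse affine and snaps to the nearest voxel with
#' round-half-away-from-zero, which is deterministic across platforms.
#'
#' @param coords numeric matrix with columns x, y, z in mm (one row per
#'   sample).
#' @param map a [term_map()].
#' @param sample_id optional ids used in error messages.
#' @return integer matrix of 1-based voxel indices (i, j, k), with
#'   attribute `linear` giving the linear index into the value array.
#' @export
sample_to_voxel <- function(coords, map, sample_id = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  inv <- solve(map$affine)
  ijk0 <- cbind(coords, 1) %*% t(inv)
  ijk <- round_half_away(ijk0[, 1:3, drop = FALSE]) + 1
  d <- dim(map$values)
  bad <- ijk[, 1] < 1 | ijk[, 1] > d[1] |
    ijk[, 2] < 1 | ijk[, 2] > d[2] |
    ijk[, 3] < 1 | ijk[, 3] > d[3]
  if (any(bad)) {
    who <- if (is.null(sample_id)) paste("row", which(bad)) else sample_id[bad]
    stop("samples outside the volume: ", paste(who, collapse = ", "))
  }
  storage.mode(ijk) <- "integer"
  attr(ijk, "linear") <- ijk[, 1] + (ijk[, 2] - 1L) * d[1] +
    (ijk[, 3] - 1L) * d[1] * d[2]
  ijk
}

#' Mask samples to positive-z voxels
#'
#' Keeps the samples whose voxel z score is strictly positive (z = 0
#' voxels carry no association signal and are excluded) and attaches the z
#' score. Negative-z voxels reflect association with other functions and
#' are likewise excluded.
#'
#' @param samples sample table with `sample_id` and mm coordinate columns
#'   `x_mm`, `y_mm`, `z_mm`.
#' @param map a [term_map()].
#' @return the retained rows of `samples` with an extra numeric column `z`.
#' @export
mask_positive <- function(samples, map) {
  if (nrow(samples) == 0L) {
    samples$z <- numeric(0)
    return(samples)
  }
  vox <- sample_to_voxel(as.matrix(samples[, c("x_mm", "y_mm", "z_mm")]), map,
                         sample_id = samples$sample_id)
  z <- map$values[attr(vox, "linear")]
  out <- samples[z > 0, , drop = FALSE]
  out$z <- z[z > 0]
  rownames(out) <- NULL
  out
}

#' Smooth expression over a spherical sample neighborhood
#'
#' Replaces each sample's value, per gene, by the unweighted mean of the
#' values at all retained samples of the same donor within Euclidean
#' distance `radius_mm` (including itself). This is a row-stochastic linear
#' operator in sample space: smoothed values stay within the per-gene range
#' of the input, and radius 0 is the identity.
#'
#' @param values numeric matrix, genes x samples.
#' @param coords numeric matrix of the samples' mm coordinates (columns x,
#'   y, z), rows parallel to the columns of `values`.
#' @param radius_mm smoothing radius in mm (>= 0).
#' @return smoothed matrix of the same shape.
#' @export
smooth_expression <- function(values, coords, radius_mm = 6) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == ncol(values))
  if (ncol(values) == 0L) return(values)
  d <- as.matrix(stats::dist(coords))
  w <- (d <= radius_mm) * 1
  w <- w / rowSums(w)
  out <- values %*% t(w)
  dimnames(out) <- dimnames(values)
  out
}

#' Pair preprocessed expression with the term map
#'
#' For each donor and compartment: samples are snapped to voxels, masked to
#' strictly positive map z, and the surviving samples' expression is
#' smoothed over a `radius_mm` sphere (masking first, so excluded samples
#' contribute nothing). Donor-compartments with no retained samples are
#' dropped and recorded in attribute `excluded`.
#'
#' @param prep output of [preprocess_study()].
#' @param samples the sample table.
#' @param map a [term_map()].
#' @param radius_mm smoothing radius in mm.
#' @return nested list `paired[[donor]][[compartment]]`, each with
#'   elements `expr` (smoothed genes x samples matrix), `z` (map z per
#'   sample) and `sample_id`.
#' @export
pair_samples <- function(prep, samples, map, radius_mm = 6) {
  paired <- list()
  excluded <- character(0)
  for (d in names(prep$matrices)) {
    for (cm in names(prep$matrices[[d]])) {
      vals <- prep$matrices[[d]][[cm]]
      smp <- samples[match(colnames(vals), samples$sample_id), ]
      kept <- mask_positive(smp, map)
      if (nrow(kept) == 0L) {
        excluded <- c(excluded, paste(d, cm, sep = "/"))
        next
      }
      vals <- vals[, kept$sample_id, drop = FALSE]
      sm <- smooth_expression(vals, as.matrix(kept[, c("x_mm", "y_mm", "z_mm")]),
                              radius_mm)
      paired[[d]][[cm]] <- list(expr = sm, z = kept$z, sample_id = kept$sample_id)
    }
  }
  attr(paired, "excluded") <- excluded
  paired
}
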