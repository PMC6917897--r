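# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding used for voxel snapping: `round()` in R rounds
#' half to even, which is platform-stable but surprising at voxel
#' boundaries; half-away-from-zero keeps the snap rule easy to reason about.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Round half up to a fixed number of decimals
#'
#' Used for reporting percentages to one decimal (e.g. 9.65 -> 9.7).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Derive a stage-specific seed from the master seed so that each generator
# stage is reproducible on its own. Offsets are fixed per stage; the result
# is kept inside the 32-bit integer range accepted by set.seed().
child_seed <- function(seed, offset) {
  (as.numeric(seed) + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
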