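.same_grid <- function(a, b, tol = 1e-6) {
  ga <- a@geometry; gb <- b@geometry
  identical(ga@dims, gb@dims) &&
    max(abs(ga@origin - gb@origin)) <= tol &&
    max(abs(ga@spacing - gb@spacing)) <= tol
}

.stop_grid_mismatch <- function(a, b)
  if (!.same_grid(a, b)) stop("masks must share the same grid")

#' Structure volume from a voxel mask
#' @param mask a \linkS4class{BinaryMask}.
#' @return volume in cm3 (set-voxel count times voxel volume).
#' @export
maskVolume <- function(mask) sum(mask@voxels) * voxelVolumeMm3(mask@geometry) / 1000

#' Centre of mass of a voxel mask
#'
#' Unweighted mean of the set-voxel centre coordinates (contours carry no
#' density information, so no intensity weighting is applied).
#'
#' @param mask a nonempty \linkS4class{BinaryMask}.
#' @return numeric(3), patient-system mm.
#' @export
centerOfMass <- function(mask) {
  pts <- .mask_points(mask)
  if (!nrow(pts)) stop("empty structure: ", mask@label)
  colMeans(pts)
}

#' Centre-of-mass distance between two masks
#'
#' Euclidean distance between the centres of mass, the positional-shift
#' measure used to quantify daily organ displacement relative to planning.
#'
#' @param maskDaily,maskPlan nonempty \linkS4class{BinaryMask} objects on the
#'   same grid.
#' @return distance in mm.
#' @export
centerOfMassDistance <- function(maskDaily, maskPlan) {
  .stop_grid_mismatch(maskDaily, maskPlan)
  sqrt(sum((centerOfMass(maskDaily) - centerOfMass(maskPlan))^2))
}

#' Dice similarity coefficient
#'
#' Volumetric overlap 2|A∩B| / (|A| + |B|) on voxel counts; 1 is perfect
#' overlap, 0 none. If exactly one mask is empty the result is 0 (true
#' disagreement); if both are empty the DSC is undefined and an error is
#' raised, which distinguishes a pipeline fault from disagreement.
#'
#' @param maskA,maskB \linkS4class{BinaryMask} objects on the same grid.
#' @return DSC in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB) {
  .stop_grid_mismatch(maskA, maskB)
  na <- sum(maskA@voxels); nb <- sum(maskB@voxels)
  if (na == 0L && nb == 0L) stop("DSC undefined: both masks empty")
  2 * sum(maskA@voxels & maskB@voxels) / (na + nb)
}

#' Isotropic margin expansion of a mask
#'
#' Morphological dilation by a Euclidean ball: a voxel is set when its
#' distance to the nearest set voxel of the input is at most \code{marginMm}.
#' The distance transform honours anisotropic spacing. Used to build the
#' "prostate + 1 cm" planning-target surrogate.
#'
#' @param mask a nonempty \linkS4class{BinaryMask}.
#' @param marginMm margin in mm, > 0.
#' @return a \linkS4class{BinaryMask} on the same grid.
#' @export
expandMargin <- function(mask, marginMm) {
  stopifnot(marginMm > 0)
  if (!any(mask@voxels)) stop("empty structure: ", mask@label)
  d2 <- edt_sq(as.logical(mask@voxels), mask@geometry@dims,
               mask@geometry@spacing)
  vox <- array(d2 <= marginMm^2 + 1e-9, mask@geometry@dims)
  BinaryMask(mask@geometry, vox,
             sprintf("%s+%gmm", mask@label, marginMm))
}
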