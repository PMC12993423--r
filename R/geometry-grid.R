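.axis_coords <- function(geom, a)
  geom@origin[a] + (seq_len(geom@dims[a]) - 1) * geom@spacing[a]

.is_axial <- function(geom, tol = 1e-3)
  max(abs(geom@orientation - diag(3))) <= tol

.stop_not_axial <- function(geom)
  if (!.is_axial(geom)) stop("only axial (identity-orientation) grids are supported")

#' Voxel volume of a grid
#' @param geom an \linkS4class{ImageGeometry}.
#' @return volume of one voxel in mm3.
#' @export
voxelVolumeMm3 <- function(geom) prod(geom@spacing)

#' Resample a grid placement to a new spacing
#'
#' Returns a new \linkS4class{ImageGeometry} with the requested spacing that
#' covers the same physical extent (the box spanned by the voxel faces). Used
#' to evaluate geometry metrics on an isotropic grid regardless of the dose
#' grid's native spacing.
#'
#' @param geom an \linkS4class{ImageGeometry}.
#' @param spacing numeric(3), target spacing in mm.
#' @return an \linkS4class{ImageGeometry}.
#' @export
resampleGeometry <- function(geom, spacing = c(1, 1, 1)) {
  .stop_not_axial(geom)
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0))
  extent <- geom@dims * geom@spacing
  dims <- pmax(1L, as.integer(ceiling(extent / spacing - 1e-9)))
  origin <- geom@origin - geom@spacing / 2 + spacing / 2
  ImageGeometry(origin, spacing, dims, geom@orientation, geom@frameOfRef)
}

# centres of the set voxels of a mask, n x 3 mm
.mask_points <- function(mask) {
  idx <- which(mask@voxels)
  if (!length(idx)) return(matrix(numeric(0), 0, 3))
  d <- mask@geometry@dims
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(mask@geometry@origin[1] + i * mask@geometry@spacing[1],
        mask@geometry@origin[2] + j * mask@geometry@spacing[2],
        mask@geometry@origin[3] + k * mask@geometry@spacing[3])
}
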