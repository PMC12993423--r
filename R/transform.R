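#' Apply a rigid registration to a contour stack
#'
#' Maps every contour vertex through the homogeneous 4x4 matrix (or its
#' inverse for \code{direction = "fixed_to_moving"}). For a pure translation
#' (rotation block equal to identity within 1e-6) the polygons stay planar and
#' are shifted exactly. When a rotation is present the transformed contours
#' are no longer axial; each contour is then re-binned by projecting its
#' vertices onto the plane at the contour's mean transformed z. The projection
#' error is bounded by the contour's in-plane radius times the sine of the
#' tilt angle, sub-voxel for the few-degree couch rotations seen online.
#'
#' @param roi a nonempty \linkS4class{Roi}.
#' @param reg a \linkS4class{RegistrationMatrix}.
#' @param direction \code{"moving_to_fixed"} (apply the matrix as stored) or
#'   \code{"fixed_to_moving"} (apply its inverse).
#' @return the transformed \linkS4class{Roi}.
#' @export
transformRoi <- function(roi, reg, direction = c("moving_to_fixed",
                                                 "fixed_to_moving")) {
  direction <- match.arg(direction)
  if (!length(roi@slices)) stop("empty structure: ", roi@name)
  M <- reg@matrix
  if (direction == "fixed_to_moving") M <- solve(M)
  R <- M[1:3, 1:3]
  t <- M[1:3, 4]
  pure_translation <- max(abs(R - diag(3))) <= 1e-6

  slices <- lapply(roi@slices, function(sl) {
    if (pure_translation) {
      polys <- lapply(sl$polygons, function(p)
        cbind(p[, 1] + t[1], p[, 2] + t[2]))
      list(z = sl$z + t[3], polygons = polys)
    } else {
      zs <- numeric(0)
      polys <- lapply(sl$polygons, function(p) {
        q <- cbind(p, sl$z) %*% t(R)
        q <- sweep(q, 2, t, "+")
        zs <<- c(zs, mean(q[, 3]))
        q[, 1:2, drop = FALSE]
      })
      list(z = mean(zs), polygons = polys)
    }
  })
  new("Roi", name = roi@name, slices = slices, color = roi@color)
}

#' Invert a registration
#' @param reg a \linkS4class{RegistrationMatrix}.
#' @return the inverse transform, with moving and fixed frames swapped.
#' @export
invertRegistration <- function(reg) {
  RegistrationMatrix(solve(reg@matrix), movingFrameId = reg@fixedFrameId,
                     fixedFrameId = reg@movingFrameId)
}
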