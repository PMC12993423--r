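#' Margin-expanded analytic shape
#'
#' The Minkowski sum of an ellipsoid with a Euclidean ball, i.e. the analytic
#' counterpart of \code{\link{expandMargin}} applied to an ellipsoidal organ.
#' @param ellipsoid an analytic ellipsoid shape (as produced by the phantom
#'   generator).
#' @param marginMm margin radius in mm.
#' @return an analytic shape usable with \code{\link{oracleSamples}}.
#' @export
marginShape <- function(ellipsoid, marginMm) {
  stopifnot(identical(ellipsoid$type, "ellipsoid"), marginMm > 0)
  list(type = "ellipsoid_margin", center = ellipsoid$center,
       semiAxes = ellipsoid$semiAxes, margin = marginMm)
}

#' Rasterization-free dose sampling of an analytic shape
#'
#' Draws quasi-random points (seeded Latin hypercube strata over the shape's
#' bounding box, rejection-sampled with the analytic inside test) and
#' interpolates the dose grid at them. This is the reference used to check
#' the voxel pipeline, because it involves no contouring, rasterization or
#' margin morphology.
#'
#' @param shape analytic shape (phantom ground truth or
#'   \code{\link{marginShape}}).
#' @param dose a \linkS4class{DoseGrid}.
#' @param nPoints number of interior points, default 1e5.
#' @param seed RNG seed.
#' @return a \linkS4class{DoseSamples} (with nominal per-sample volume
#'   \code{volume/n} when the analytic volume is known).
#' @export
oracleSamples <- function(shape, dose, nPoints = 1e5, seed = 1L) {
  bb <- .shape_bbox(shape)
  span <- bb$hi - bb$lo
  vol <- .shape_volume(shape)
  frac <- if (is.na(vol)) 0.3 else vol / prod(span)
  set.seed(seed)
  acc <- NULL
  got <- 0L
  while (got < nPoints) {
    ndraw <- min(2e6, max(10000, ceiling((nPoints - got) / max(frac, 0.02) *
                                           1.2)))
    u <- lhs::randomLHS(ndraw, 3)
    pts <- sweep(sweep(u, 2, span, "*"), 2, bb$lo, "+")
    keep <- .shape_inside(shape, pts)
    frac <- max(mean(keep), 1e-3)
    pts <- pts[keep, , drop = FALSE]
    acc <- if (is.null(acc)) pts else rbind(acc, pts)
    got <- nrow(acc)
  }
  acc <- acc[seq_len(nPoints), , drop = FALSE]
  v <- trilinear(as.numeric(dose@values), dose@geometry@dims,
                 dose@geometry@origin, dose@geometry@spacing, acc)
  nout <- sum(is.na(v))
  if (nout == nPoints) stop("shape lies entirely outside the dose grid")
  volcm3 <- if (is.na(vol)) NA_real_ else vol / 1000
  .dose_samples(pmax(v[!is.na(v)], 0),
                voxelVolumeCm3 = if (is.na(volcm3)) 0 else
                  volcm3 / (nPoints - nout),
                structure = "oracle", nOutsideGrid = nout)
}

#' Oracle dose metrics of an analytic shape
#'
#' @inheritParams oracleSamples
#' @return the standard metric block (see \code{\link{doseMetrics}}).
#' @export
oracleMetrics <- function(shape, dose, nPoints = 1e5, seed = 1L)
  doseMetrics(oracleSamples(shape, dose, nPoints = nPoints, seed = seed))
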