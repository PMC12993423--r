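#' Sample the plan dose inside a structure mask
#'
#' Interpolates the dose grid at the centres of the mask's set voxels
#' (trilinear by default; nearest-neighbour retained for oracle comparison).
#' Voxel centres outside the dose grid are excluded and counted; when their
#' fraction exceeds \code{maxOutsideFrac} (default 5\%, the tolerance adopted
#' for truncated daily imaging) an error is raised, and
#' \code{outsidePolicy = "error"} makes any outside voxel fatal.
#'
#' @param mask a nonempty \linkS4class{BinaryMask}; must share the dose
#'   grid's frame of reference.
#' @param dose a \linkS4class{DoseGrid}.
#' @param method interpolation, \code{"trilinear"} or \code{"nearest"}.
#' @param maxOutsideFrac maximum tolerated fraction of voxels outside the
#'   dose grid.
#' @param outsidePolicy \code{"exclude"} (count and drop) or \code{"error"}.
#' @return a \linkS4class{DoseSamples}.
#' @export
sampleDose <- function(mask, dose, method = c("trilinear", "nearest"),
                       maxOutsideFrac = 0.05,
                       outsidePolicy = c("exclude", "error")) {
  method <- match.arg(method)
  outsidePolicy <- match.arg(outsidePolicy)
  if (!identical(mask@geometry@frameOfRef, dose@geometry@frameOfRef))
    stop(sprintf("frame-of-reference mismatch: mask '%s' vs dose '%s'",
                 mask@geometry@frameOfRef, dose@geometry@frameOfRef))
  .stop_not_axial(dose@geometry)
  pts <- .mask_points(mask)
  if (!nrow(pts)) stop("empty structure: ", mask@label)
  f <- if (method == "trilinear") trilinear else nearest_sample
  v <- f(as.numeric(dose@values), dose@geometry@dims, dose@geometry@origin,
         dose@geometry@spacing, pts)
  nout <- sum(is.na(v))
  if (nout == nrow(pts))
    stop(sprintf("structure '%s' lies entirely outside the dose grid",
                 mask@label))
  if (outsidePolicy == "error" && nout > 0L)
    stop(sprintf("%d voxel(s) of '%s' outside the dose grid", nout,
                 mask@label))
  if (nout / nrow(pts) > maxOutsideFrac)
    stop(sprintf("%.1f%% of '%s' outside the dose grid (tolerance %.1f%%)",
                 100 * nout / nrow(pts), mask@label, 100 * maxOutsideFrac))
  new("DoseSamples", values = pmax(v[!is.na(v)], 0),
      voxelVolumeCm3 = voxelVolumeMm3(mask@geometry) / 1000,
      nOutsideGrid = as.integer(nout), structure = mask@label)
}

.dose_samples <- function(values, voxelVolumeCm3 = 0.001, structure = "",
                          nOutsideGrid = 0L)
  new("DoseSamples", values = as.numeric(values),
      voxelVolumeCm3 = voxelVolumeCm3, nOutsideGrid = as.integer(nOutsideGrid),
      structure = as.character(structure))

#' Cumulative DVH from dose samples
#'
#' Bins the sampled dose on a fixed-width axis starting at 0;
#' \code{cumVolumePct[k]} is 100 times the fraction of samples with dose at
#' least \code{doseAxis[k]}. The axis always reaches the maximum sample.
#'
#' @param samples a nonempty \linkS4class{DoseSamples}.
#' @param binWidthGy axis step in Gy, default 0.1.
#' @return a \linkS4class{DvhCurve}.
#' @export
cumulativeDvh <- function(samples, binWidthGy = 0.1) {
  stopifnot(binWidthGy > 0)
  v <- samples@values
  if (!length(v)) stop("empty structure: ", samples@structure)
  K <- max(1L, as.integer(ceiling(max(v) / binWidthGy - 1e-9)))
  # bin index with boundary values (v == k*w) counted as >= k*w
  idx <- pmin(as.integer(floor(v / binWidthGy + 1e-9)), K)
  cnt <- tabulate(idx + 1L, nbins = K + 1L)
  surv <- rev(cumsum(rev(cnt))) / length(v) * 100
  new("DvhCurve", doseAxis = (0:K) * binWidthGy, cumVolumePct = surv,
      structure = samples@structure,
      totalVolumeCm3 = length(v) * samples@voxelVolumeCm3,
      binWidthGy = binWidthGy)
}

#' @name dvh-metrics
#' @title ICRU-83 style dose-volume metrics
#' @description
#' \code{doseAtVolume(x, xPct)} is D_x\%: the minimum dose received by the
#' hottest \code{xPct}\% of the structure volume, i.e. the (100 - x)th
#' percentile of the dose distribution. \code{volumeAtDose(x, xGy)} is
#' V_xGy: the percentage of the volume receiving at least \code{xGy}.
#' \code{meanDose(x)} is the volume-weighted mean dose.
#'
#' On \linkS4class{DoseSamples} the metrics are exact: percentiles use linear
#' interpolation between order statistics (\code{\link[stats]{quantile}} type
#' 7) and V_xGy is a direct count. On a \linkS4class{DvhCurve} they are read
#' off the binned curve by linear interpolation (D_x from the dose where the
#' curve crosses x\%, mean dose by trapezoidal integration of the curve), so
#' they agree with the sample versions to within one bin width.
#' @param x a \linkS4class{DoseSamples} or \linkS4class{DvhCurve}.
#' @param xPct volume percentage in (0, 100).
#' @param xGy dose threshold in Gy, >= 0.
NULL

#' @rdname dvh-metrics
#' @export
setGeneric("doseAtVolume", function(x, xPct) standardGeneric("doseAtVolume"))

#' @rdname dvh-metrics
#' @export
setGeneric("volumeAtDose", function(x, xGy) standardGeneric("volumeAtDose"))

#' @rdname dvh-metrics
#' @export
setGeneric("meanDose", function(x) standardGeneric("meanDose"))

#' @export
setMethod("doseAtVolume", "DoseSamples", function(x, xPct) {
  if (xPct <= 0 || xPct >= 100) stop("xPct must lie in (0, 100)")
  if (!length(x@values)) stop("empty structure")
  stats::quantile(x@values, probs = 1 - xPct / 100, type = 7, names = FALSE)
})

#' @export
setMethod("volumeAtDose", "DoseSamples", function(x, xGy) {
  stopifnot(xGy >= 0)
  100 * mean(x@values >= xGy)
})

#' @export
setMethod("meanDose", "DoseSamples", function(x) {
  if (!length(x@values)) stop("empty structure")
  mean(x@values)
})

#' @export
setMethod("doseAtVolume", "DvhCurve", function(x, xPct) {
  if (xPct <= 0 || xPct >= 100) stop("xPct must lie in (0, 100)")
  S <- x@cumVolumePct
  ax <- x@doseAxis
  k <- max(which(S >= xPct - 1e-12))
  if (k == length(S)) return(ax[k])
  drop <- S[k] - S[k + 1]
  if (drop <= 1e-12) return(ax[k])
  ax[k] + x@binWidthGy * (S[k] - xPct) / drop
})

#' @export
setMethod("volumeAtDose", "DvhCurve", function(x, xGy) {
  stopifnot(xGy >= 0)
  if (xGy >= max(x@doseAxis)) {
    if (xGy > max(x@doseAxis)) return(0)
    return(x@cumVolumePct[length(x@cumVolumePct)])
  }
  stats::approx(x@doseAxis, x@cumVolumePct, xout = xGy)$y
})

#' @export
setMethod("meanDose", "DvhCurve", function(x) {
  S <- x@cumVolumePct / 100
  K <- length(S)
  x@binWidthGy * (sum(S) - (S[1] + S[K]) / 2)
})

#' The standard metric block
#'
#' D98\%, D50\%, D2\%, mean dose (Gy) and V20Gy, V50Gy (\% volume), the dose
#' reporting set used throughout the course analysis.
#'
#' @param x a \linkS4class{DoseSamples} or \linkS4class{DvhCurve}.
#' @param vDosesGy dose levels for the V_xGy metrics, default c(20, 50).
#' @return named numeric vector \code{D98_Gy, D50_Gy, D2_Gy, Dmean_Gy,
#'   V20Gy_pct, V50Gy_pct}.
#' @export
doseMetrics <- function(x, vDosesGy = c(20, 50)) {
  out <- c(D98_Gy = doseAtVolume(x, 98), D50_Gy = doseAtVolume(x, 50),
           D2_Gy = doseAtVolume(x, 2), Dmean_Gy = meanDose(x))
  for (dgy in vDosesGy)
    out[sprintf("V%gGy_pct", dgy)] <- volumeAtDose(x, dgy)
  out
}

#' Export a DVH curve as CSV
#' @param curve a \linkS4class{DvhCurve}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDvhCsv <- function(curve, path) {
  utils::write.csv(data.frame(dose_gy = curve@doseAxis,
                              volume_pct = curve@cumVolumePct),
                   path, row.names = FALSE)
  invisible(path)
}
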