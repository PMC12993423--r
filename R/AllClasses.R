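#' @import methods
NULL

.is_orthonormal <- function(M, tol) {
  is.matrix(M) && all(dim(M) == c(3L, 3L)) &&
    max(abs(crossprod(M) - diag(3))) <= tol
}

#' Regular 3-D image grid placement
#'
#' Describes where a regular voxel grid sits in the patient coordinate system
#' (DICOM convention: x right-to-left, y anterior-to-posterior, z
#' inferior-to-superior, all millimetres). \code{origin} is the centre of the
#' first voxel; voxel \code{(i, j, k)} (1-based) has centre
#' \code{origin + (i-1, j-1, k-1) * spacing} for an axial orientation.
#'
#' @slot origin numeric(3), mm.
#' @slot spacing numeric(3), mm per voxel, all positive.
#' @slot dims integer(3), grid size, all at least 1.
#' @slot orientation 3x3 direction-cosine matrix, orthonormal.
#' @slot frameOfRef opaque frame-of-reference identifier.
#' @export
setClass("ImageGeometry",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 orientation = "matrix", frameOfRef = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values")
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be 3 integers >= 1")
    if (!.is_orthonormal(object@orientation, 1e-6))
      msg <- c(msg, "orientation must be orthonormal within 1e-6")
    if (length(msg)) msg else TRUE
  })

#' @param origin,spacing,dims,orientation,frameOfRef see slots.
#' @rdname ImageGeometry-class
#' @export
ImageGeometry <- function(origin, spacing, dims, orientation = diag(3),
                          frameOfRef = "FOR") {
  new("ImageGeometry", origin = as.numeric(origin),
      spacing = as.numeric(spacing), dims = as.integer(dims),
      orientation = orientation, frameOfRef = as.character(frameOfRef))
}

#' Planned absorbed-dose grid
#'
#' A 3-D scalar field of absorbed dose in Gy on an \linkS4class{ImageGeometry},
#' already scaled to physical units (readers multiply stored integers by the
#' stored scaling factor). This is the baseline plan dose that every daily and
#' accumulated DVH is evaluated against.
#'
#' @slot geometry \linkS4class{ImageGeometry}.
#' @slot values 3-D numeric array, Gy, non-negative, shape \code{dims(geometry)}.
#' @slot doseUnits character, only \code{"GY"} supported.
#' @slot summationType free-text provenance tag (e.g. \code{"PLAN"}).
#' @export
setClass("DoseGrid",
  representation(geometry = "ImageGeometry", values = "array",
                 doseUnits = "character", summationType = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@geometry@dims)))
      msg <- c(msg, "values shape must equal geometry dims")
    if (any(object@values < 0)) msg <- c(msg, "dose values must be >= 0")
    if (!identical(object@doseUnits, "GY"))
      msg <- c(msg, "doseUnits must be 'GY'")
    if (length(msg)) msg else TRUE
  })

#' @param geometry,values,doseUnits,summationType see slots.
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(geometry, values, doseUnits = "GY",
                     summationType = "PLAN") {
  new("DoseGrid", geometry = geometry, values = values, doseUnits = doseUnits,
      summationType = summationType)
}

#' Region of interest as a stack of planar contours
#'
#' One named structure (organ) as closed planar polygons grouped by axial
#' plane. Coordinates are patient-system millimetres; the first vertex of each
#' polygon is implicitly joined to the last. Degenerate contours (fewer than 3
#' vertices, or zero area) are dropped by \code{Roi()} with a warning.
#'
#' @slot name structure name.
#' @slot slices list of \code{list(z = <mm>, polygons = list of n x 2 matrices)}.
#' @slot color RGB triple in 0..255 (display metadata only).
#' @export
setClass("Roi",
  representation(name = "character", slices = "list", color = "numeric"),
  validity = function(object) {
    for (sl in object@slices) {
      if (!is.numeric(sl$z) || length(sl$z) != 1L)
        return("each slice needs a scalar z")
      for (p in sl$polygons) {
        if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
          return("polygons must be n x 2 matrices with n >= 3")
      }
    }
    TRUE
  })

.polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' @param name,slices,color see slots.
#' @rdname Roi-class
#' @export
Roi <- function(name, slices, color = c(255, 0, 0)) {
  dropped <- 0L
  slices <- lapply(slices, function(sl) {
    keep <- vapply(sl$polygons, function(p) {
      is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L && .polygon_area(p) > 0
    }, logical(1))
    dropped <<- dropped + sum(!keep)
    list(z = as.numeric(sl$z), polygons = sl$polygons[keep])
  })
  slices <- slices[vapply(slices, function(sl) length(sl$polygons) > 0L,
                          logical(1))]
  if (dropped > 0L)
    warning(sprintf("Roi '%s': dropped %d degenerate contour(s)", name,
                    dropped))
  new("Roi", name = as.character(name), slices = slices,
      color = as.numeric(color))
}

#' Named collection of ROIs sharing a frame of reference
#'
#' @slot rois named list of \linkS4class{Roi}; names unique case-insensitively.
#' @slot frameOfRef frame-of-reference identifier of the image the contours
#'   were drawn on.
#' @slot sourceImageId identifier of the source image series.
#' @export
setClass("StructureSet",
  representation(rois = "list", frameOfRef = "character",
                 sourceImageId = "character"),
  validity = function(object) {
    nm <- names(object@rois)
    if (is.null(nm) || anyDuplicated(tolower(nm)))
      return("roi names must be unique (case-insensitive)")
    if (!all(vapply(object@rois, is, logical(1), "Roi")))
      return("rois must all be Roi objects")
    TRUE
  })

#' @param rois,frameOfRef,sourceImageId see slots.
#' @rdname StructureSet-class
#' @export
StructureSet <- function(rois, frameOfRef = "FOR", sourceImageId = "IMG") {
  if (is.null(names(rois)))
    names(rois) <- vapply(rois, function(r) r@name, character(1))
  new("StructureSet", rois = rois, frameOfRef = as.character(frameOfRef),
      sourceImageId = as.character(sourceImageId))
}

#' Rigid 4x4 registration transform
#'
#' Homogeneous transform between the daily (moving) image frame and the
#' planning (fixed) frame, as recorded by the online positioning system. The
#' upper-left 3x3 block must be orthogonal (rigid) within 1e-4.
#'
#' @slot matrix 4x4 numeric, last row (0, 0, 0, 1).
#' @slot movingFrameId,fixedFrameId frame identifiers.
#' @export
setClass("RegistrationMatrix",
  representation(matrix = "matrix", movingFrameId = "character",
                 fixedFrameId = "character"),
  validity = function(object) {
    M <- object@matrix
    if (!all(dim(M) == c(4L, 4L))) return("matrix must be 4x4")
    if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9)
      return("last row must be (0, 0, 0, 1)")
    R <- M[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-4)
      return("upper-left 3x3 block is not rigid (tolerance 1e-4)")
    TRUE
  })

#' @param matrix,movingFrameId,fixedFrameId see slots.
#' @rdname RegistrationMatrix-class
#' @export
RegistrationMatrix <- function(matrix, movingFrameId = "MOVING",
                               fixedFrameId = "FIXED") {
  new("RegistrationMatrix", matrix = matrix,
      movingFrameId = as.character(movingFrameId),
      fixedFrameId = as.character(fixedFrameId))
}

#' One treatment session: daily contours plus the online registration
#'
#' @slot index 1-based fraction number, unique within a course.
#' @slot structures daily \linkS4class{StructureSet}.
#' @slot registration \linkS4class{RegistrationMatrix} mapping the daily frame
#'   to the planning frame (or the reverse; the course manifest records the
#'   direction).
#' @slot label free-text acquisition label.
#' @export
setClass("FractionRecord",
  representation(index = "integer", structures = "StructureSet",
                 registration = "RegistrationMatrix", label = "character"))

#' @param index,structures,registration,label see slots.
#' @rdname FractionRecord-class
#' @export
FractionRecord <- function(index, structures, registration, label = "") {
  new("FractionRecord", index = as.integer(index), structures = structures,
      registration = registration, label = as.character(label))
}

#' A complete treatment course
#'
#' Planning structures and plan dose (sharing one frame of reference) plus the
#' ordered daily fraction records.
#'
#' @slot planningStructures \linkS4class{StructureSet} on the planning CT.
#' @slot planDose baseline \linkS4class{DoseGrid}.
#' @slot fractions list of \linkS4class{FractionRecord}, sorted by index.
#' @slot nFractionsPlanned prescribed number of fractions.
#' @slot matrixMaps either \code{"moving_to_fixed"} (daily-to-planning, the
#'   default) or \code{"fixed_to_moving"}; direction convention of the stored
#'   registration matrices.
#' @export
setClass("TreatmentCourse",
  representation(planningStructures = "StructureSet", planDose = "DoseGrid",
                 fractions = "list", nFractionsPlanned = "integer",
                 matrixMaps = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(object@planningStructures@frameOfRef,
                   object@planDose@geometry@frameOfRef))
      msg <- c(msg, "plan dose and planning structures must share a frame of reference")
    idx <- vapply(object@fractions, function(f) f@index, integer(1))
    if (anyDuplicated(idx)) msg <- c(msg, "duplicate fraction index")
    if (is.unsorted(idx)) msg <- c(msg, "fractions must be sorted by index")
    if (!object@matrixMaps %in% c("moving_to_fixed", "fixed_to_moving"))
      msg <- c(msg, "matrixMaps must be moving_to_fixed or fixed_to_moving")
    if (length(msg)) msg else TRUE
  })

#' @param planningStructures,planDose,fractions,nFractionsPlanned,matrixMaps
#'   see slots. Fractions are sorted by index on construction.
#' @rdname TreatmentCourse-class
#' @export
TreatmentCourse <- function(planningStructures, planDose, fractions,
                            nFractionsPlanned = length(fractions),
                            matrixMaps = "moving_to_fixed") {
  idx <- vapply(fractions, function(f) f@index, integer(1))
  if (anyDuplicated(idx))
    stop("duplicate fraction index: ",
         paste(idx[duplicated(idx)], collapse = ", "))
  new("TreatmentCourse", planningStructures = planningStructures,
      planDose = planDose, fractions = fractions[order(idx)],
      nFractionsPlanned = as.integer(nFractionsPlanned),
      matrixMaps = matrixMaps)
}

#' Voxelized structure mask
#'
#' @slot geometry \linkS4class{ImageGeometry} the mask lives on.
#' @slot voxels 3-D logical array, shape \code{dims(geometry)}.
#' @slot label structure name.
#' @export
setClass("BinaryMask",
  representation(geometry = "ImageGeometry", voxels = "array",
                 label = "character"),
  validity = function(object) {
    if (!identical(dim(object@voxels), as.integer(object@geometry@dims)))
      return("voxels shape must equal geometry dims")
    if (!is.logical(object@voxels)) return("voxels must be logical")
    TRUE
  })

#' @param geometry,voxels,label see slots.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(geometry, voxels, label = "") {
  new("BinaryMask", geometry = geometry, voxels = voxels,
      label = as.character(label))
}

#' Dose samples inside a structure
#'
#' Plan dose interpolated at the centres of a structure's set voxels.
#'
#' @slot values numeric, Gy, one value per in-grid voxel.
#' @slot voxelVolumeCm3 volume represented by each sample.
#' @slot nOutsideGrid number of structure voxels whose centres fell outside
#'   the dose grid (excluded from \code{values}).
#' @slot structure structure name.
#' @export
setClass("DoseSamples",
  representation(values = "numeric", voxelVolumeCm3 = "numeric",
                 nOutsideGrid = "integer", structure = "character"),
  validity = function(object) {
    if (any(object@values < 0)) return("dose samples must be >= 0")
    if (object@nOutsideGrid < 0L) return("nOutsideGrid must be >= 0")
    TRUE
  })

#' Cumulative dose-volume histogram
#'
#' Relative cumulative DVH: \code{cumVolumePct[k]} is the percentage of the
#' structure volume receiving at least \code{doseAxis[k]} Gy. The axis starts
#' at 0 with fixed bin width and covers the maximum sampled dose.
#'
#' @slot doseAxis ascending dose axis, Gy.
#' @slot cumVolumePct non-increasing values in [0, 100]; 100 at dose 0 for a
#'   nonempty structure.
#' @slot structure structure name.
#' @slot totalVolumeCm3 absolute structure volume.
#' @slot binWidthGy axis step, Gy.
#' @export
setClass("DvhCurve",
  representation(doseAxis = "numeric", cumVolumePct = "numeric",
                 structure = "character", totalVolumeCm3 = "numeric",
                 binWidthGy = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@doseAxis) != length(object@cumVolumePct))
      msg <- c(msg, "axis and values must have equal length")
    if (any(diff(object@cumVolumePct) > 1e-9))
      msg <- c(msg, "cumulative DVH must be non-increasing")
    if (any(object@cumVolumePct < -1e-9 | object@cumVolumePct > 100 + 1e-9))
      msg <- c(msg, "cumVolumePct must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' Per-course baseline evaluation
#'
#' Metrics and curves of the planning structures on the plan dose, computed
#' once per course. \code{metrics} hold exact (raw-sample) percentile metrics;
#' \code{curveMetrics} hold the same metrics read off the binned curve with
#' the estimator used for accumulated curves, so that deviations compare like
#' with like.
#'
#' @slot structures structure names evaluated (including the auto-generated
#'   margin target).
#' @slot metrics,curveMetrics named lists of named numeric metric vectors.
#' @slot curves named list of \linkS4class{DvhCurve}.
#' @slot masks named list of \linkS4class{BinaryMask} in the planning frame.
#' @slot volumes named numeric, cm3.
#' @export
setClass("Baseline",
  representation(structures = "character", metrics = "list",
                 curveMetrics = "list", curves = "list", masks = "list",
                 volumes = "numeric"))

#' Evaluation of a single fraction
#'
#' @slot index fraction index.
#' @slot geometry named list of geometry summaries (volume_cm3,
#'   volume_dev_pct, com, cmd_mm, dsc) per structure.
#' @slot metrics named list of metric vectors (plan-total Gy units).
#' @slot deviations named list of metric deviation percentages vs baseline.
#' @slot curves named list of \linkS4class{DvhCurve}.
#' @export
setClass("FractionResult",
  representation(index = "integer", geometry = "list", metrics = "list",
                 deviations = "list", curves = "list"))

#' Accumulated-course estimate
#'
#' @slot curves named list of accumulated \linkS4class{DvhCurve} (equal-weight
#'   mean of daily curves).
#' @slot metrics named list of metric vectors read off the accumulated curves.
#' @slot deviationPct named list of deviation percentages vs baseline
#'   (curve-estimator baseline); NA where the baseline metric is 0.
#' @slot flags named list of logical vectors, TRUE where |deviation| exceeds
#'   the relevance threshold.
#' @slot nAvailable number of fractions averaged.
#' @slot thresholdPct relevance threshold used, percent.
#' @export
setClass("AccumulatedResult",
  representation(curves = "list", metrics = "list", deviationPct = "list",
                 flags = "list", nAvailable = "integer",
                 thresholdPct = "numeric"))

#' Full course report
#'
#' @slot baseline \linkS4class{Baseline}.
#' @slot fractionResults list of \linkS4class{FractionResult}.
#' @slot accumulated \linkS4class{AccumulatedResult}.
#' @slot failures named list of error messages for fractions that failed in
#'   lenient mode.
#' @slot stats summary statistics tables (see \code{\link{runCourse}}).
#' @slot timings named numeric, seconds per pipeline stage.
#' @slot config evaluation configuration used.
#' @export
setClass("CourseReport",
  representation(baseline = "Baseline", fractionResults = "list",
                 accumulated = "AccumulatedResult", failures = "list",
                 stats = "list", timings = "numeric", config = "list"))
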