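#' @name doseacc-accessors
#' @title Accessors for the core data classes
#' @param x an object of the documented class.
#' @param name a structure name (case-insensitive for lookup).
NULL

#' @describeIn doseacc-accessors grid placement of a DoseGrid or BinaryMask.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @export
setMethod("geometry", "DoseGrid", function(x) x@geometry)
#' @export
setMethod("geometry", "BinaryMask", function(x) x@geometry)

#' @describeIn doseacc-accessors 3-D dose array in Gy.
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))
#' @export
setMethod("doseValues", "DoseGrid", function(x) x@values)

#' @describeIn doseacc-accessors names of the ROIs in a StructureSet.
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @export
setMethod("roiNames", "StructureSet", function(x) names(x@rois))

#' @describeIn doseacc-accessors fetch one ROI by (case-insensitive) name.
#' @export
setGeneric("getRoi", function(x, name) standardGeneric("getRoi"))
#' @export
setMethod("getRoi", "StructureSet", function(x, name) {
  hit <- match(tolower(name), tolower(names(x@rois)))
  if (is.na(hit))
    stop(sprintf("structure '%s' not found; available: %s", name,
                 paste(names(x@rois), collapse = ", ")))
  x@rois[[hit]]
})

#' @describeIn doseacc-accessors number of fraction records in a course.
#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))
#' @export
setMethod("nFractions", "TreatmentCourse", function(x) length(x@fractions))

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf("ImageGeometry %dx%dx%d @ (%.2f, %.2f, %.2f) mm, spacing (%g, %g, %g) mm [%s]\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@origin[1], object@origin[2], object@origin[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@frameOfRef))
})

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid (%s, %s): max %.2f Gy\n", object@doseUnits,
              object@summationType, max(object@values)))
  show(object@geometry)
})

setMethod("show", "Roi", function(object) {
  np <- sum(vapply(object@slices, function(s) length(s$polygons), integer(1)))
  cat(sprintf("Roi '%s': %d plane(s), %d polygon(s)\n", object@name,
              length(object@slices), np))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet [%s]: %s\n", object@frameOfRef,
              paste(names(object@rois), collapse = ", ")))
})

setMethod("show", "RegistrationMatrix", function(object) {
  cat(sprintf("RegistrationMatrix %s -> %s\n", object@movingFrameId,
              object@fixedFrameId))
  print(round(object@matrix, 6))
})

setMethod("show", "TreatmentCourse", function(object) {
  cat(sprintf("TreatmentCourse: %d/%d fraction(s), structures: %s\n",
              length(object@fractions), object@nFractionsPlanned,
              paste(names(object@planningStructures@rois), collapse = ", ")))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask '%s': %d set voxel(s)\n", object@label,
              sum(object@voxels)))
})

setMethod("show", "DvhCurve", function(object) {
  cat(sprintf("DvhCurve '%s': %d bins of %g Gy, volume %.2f cm3\n",
              object@structure, length(object@doseAxis), object@binWidthGy,
              object@totalVolumeCm3))
})

setMethod("show", "CourseReport", function(object) {
  cat(sprintf("CourseReport: %d fraction(s) evaluated (%d failed), structures: %s\n",
              length(object@fractionResults), length(object@failures),
              paste(object@baseline@structures, collapse = ", ")))
  nf <- sum(unlist(object@accumulated@flags))
  cat(sprintf("  accumulated metrics beyond %.3g%% threshold: %d\n",
              object@accumulated@thresholdPct, nf))
})
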