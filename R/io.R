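#' @name course-io
#' @title Reading and writing course data
#' @description
#' Course data are exchanged as plain-text files: dose grids and structure
#' sets as JSON documents, registration matrices in a 4-line whitespace
#' separated text dialect (row-major), and a whole course as a YAML manifest
#' naming the per-fraction files. Dose grids store integer values plus a
#' scaling factor (values = stored x scaling, in Gy), so write-then-read
#' round trips are exact to one scaling quantum; contour vertices round-trip
#' within 1e-3 mm. All coordinates are patient-system millimetres.
NULL

#' @describeIn course-io read a dose grid.
#' @param path file path.
#' @return \code{readDoseGrid}: a \linkS4class{DoseGrid}.
#' @export
readDoseGrid <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(d$scaling)) stop("dose format error: missing scaling factor")
  if (is.null(d$dose_units) || !identical(toupper(d$dose_units), "GY"))
    stop("unsupported dose units: ", d$dose_units)
  offs <- as.numeric(d$slice_offsets)
  if (length(offs) >= 2) {
    steps <- diff(offs)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-3)
      stop("nonuniform grid: slice offsets ",
           paste(utils::head(offs, 5), collapse = ", "), " ...")
    dz <- steps[1]
  } else dz <- as.numeric(d$spacing)[3]
  dims <- as.integer(d$dims)
  geom <- ImageGeometry(as.numeric(d$origin),
                        c(as.numeric(d$spacing)[1:2], dz), dims,
                        frameOfRef = d$frame_of_reference)
  vals <- array(as.numeric(d$stored_values) * d$scaling, dims)
  DoseGrid(geom, vals, summationType = d$summation_type %||% "PLAN")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn course-io write a dose grid (values quantized by
#'   \code{scaling}).
#' @param dose a \linkS4class{DoseGrid}.
#' @param scaling quantum in Gy for the stored integers, default 0.001.
#' @export
writeDoseGrid <- function(dose, path, scaling = 0.001) {
  g <- dose@geometry
  doc <- list(type = "doseacc.dose", frame_of_reference = g@frameOfRef,
              origin = g@origin, spacing = g@spacing, dims = g@dims,
              slice_offsets = (seq_len(g@dims[3]) - 1) * g@spacing[3],
              scaling = scaling, dose_units = dose@doseUnits,
              summation_type = dose@summationType,
              stored_values = as.integer(round(as.numeric(dose@values) /
                                                 scaling)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn course-io read a structure set. Non-CLOSED_PLANAR ROIs are
#'   skipped with a warning; degenerate contours (< 3 vertices or zero area)
#'   are dropped with a warning; zero usable ROIs is an error.
#' @return \code{readStructureSet}: a \linkS4class{StructureSet}.
#' @export
readStructureSet <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rois <- list()
  for (r in d$rois) {
    gt <- r$geometric_type %||% "CLOSED_PLANAR"
    if (!identical(gt, "CLOSED_PLANAR")) {
      warning(sprintf("ROI '%s': skipping geometric type %s", r$name, gt))
      next
    }
    slices <- lapply(r$slices, function(sl) {
      polys <- lapply(sl$polygons, function(p)
        do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))
      list(z = as.numeric(sl$z), polygons = polys)
    })
    roi <- Roi(r$name, slices, color = as.numeric(unlist(r$color %||%
                                                           c(255, 0, 0))))
    if (length(roi@slices)) rois[[r$name]] <- roi
  }
  if (!length(rois)) stop("empty structure set: no usable ROIs in ", path)
  StructureSet(rois, frameOfRef = d$frame_of_reference,
               sourceImageId = d$source_image %||% "IMG")
}

#' @describeIn course-io write a structure set.
#' @param ss a \linkS4class{StructureSet}.
#' @export
writeStructureSet <- function(ss, path) {
  rois <- lapply(ss@rois, function(r) {
    list(name = r@name, color = r@color, geometric_type = "CLOSED_PLANAR",
         slices = lapply(r@slices, function(sl)
           list(z = sl$z, polygons = lapply(sl$polygons, function(p)
             lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))))))
  })
  doc <- list(type = "doseacc.structures",
              frame_of_reference = ss@frameOfRef,
              source_image = ss@sourceImageId, rois = unname(rois))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @describeIn course-io read a registration matrix from the 4-line text
#'   dialect (row-major, whitespace separated). Rigidity is checked with
#'   tolerance 1e-4; the text dialect carries no frame identifiers, so
#'   placeholder ids are assigned.
#' @return \code{readRegistration}: a \linkS4class{RegistrationMatrix}.
#' @export
readRegistration <- function(path) {
  vals <- scan(path, quiet = TRUE, comment.char = "#")
  if (length(vals) != 16L)
    stop("registration format error: expected 16 numbers, got ", length(vals))
  RegistrationMatrix(matrix(vals, 4, 4, byrow = TRUE),
                     movingFrameId = "MOVING", fixedFrameId = "FIXED")
}

#' @describeIn course-io write a registration matrix as text.
#' @param reg a \linkS4class{RegistrationMatrix}.
#' @export
writeRegistration <- function(reg, path) {
  writeLines(apply(reg@matrix, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), path)
  invisible(path)
}

#' @describeIn course-io load a complete course from a YAML manifest. The
#'   manifest names the planning structure set and plan dose plus one
#'   (structures, registration) pair per fraction; paths are relative to the
#'   manifest. Missing files are reported in one aggregate error; duplicate
#'   fraction indices are an error; fractions are sorted by index.
#' @param manifest path to the YAML manifest.
#' @return \code{loadCourse}: a \linkS4class{TreatmentCourse}.
#' @export
loadCourse <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  base <- dirname(normalizePath(manifest))
  rel <- function(p) file.path(base, p)
  need <- c(rel(m$planning$structures), rel(m$planning$dose),
            unlist(lapply(m$fractions, function(f)
              c(rel(f$structures), rel(f$registration)))))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing course file(s): ", paste(missing, collapse = ", "))
  idx <- vapply(m$fractions, function(f) as.integer(f$index), integer(1))
  if (anyDuplicated(idx))
    stop("duplicate fraction index: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  plan_ss <- readStructureSet(rel(m$planning$structures))
  plan_dose <- readDoseGrid(rel(m$planning$dose))
  fx <- lapply(m$fractions, function(f)
    FractionRecord(f$index, readStructureSet(rel(f$structures)),
                   readRegistration(rel(f$registration)),
                   label = f$label %||% sprintf("fx%03d", f$index)))
  TreatmentCourse(plan_ss, plan_dose, fx,
                  nFractionsPlanned = as.integer(m$n_fractions_planned %||%
                                                   length(fx)),
                  matrixMaps = m$matrix_maps %||% "moving_to_fixed")
}
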