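#' Configuration of the synthetic pelvic phantom
#'
#' Builds the parameter set for the synthetic treatment-course generator. The
#' phantom emulates a prostate radiotherapy course: a planning anatomy (body,
#' bladder, rectum, prostate as analytic shapes), a planned dose plateau over
#' the prostate plus margin with a smooth sigmoidal falloff, and N daily
#' fraction anatomies with lognormal organ-volume variation (bladder much
#' larger than rectum, rectum larger than prostate), Gaussian prostate
#' displacement of a few mm, and a rigid setup error that is recorded
#' inversely in the emitted registration matrix (so applying the matrix
#' restores everything except the true anatomical change).
#'
#' Defaults reproduce the study conditions the generator is meant to emulate:
#' 60 Gy in 20 fractions; baseline organ volumes equal to typical cohort
#' means (prostate 42.2, bladder 205.9, rectum 73.5 cm3); interfractional
#' volume coefficients of variation 35.2\% (bladder), 20.6\% (rectum), 9.5\%
#' (prostate); per-axis prostate displacement SD 2.10 mm, giving a mean 3-D
#' displacement of 2.10 x sqrt(8/pi) = 3.35 mm.
#'
#' @param seed integer RNG seed; the whole course is a deterministic function
#'   of the configuration.
#' @param nFractions number of daily fractions, default 20.
#' @param planDoseGy prescription (plan total) dose in Gy, default 60.
#' @param doseSpacingMm dose-grid spacing, default c(2, 2, 2).
#' @param ctSpacingMm CT/contour grid spacing, default c(1, 1, 3); contours
#'   are emitted at the CT slice positions.
#' @param prostateSemiAxesMm,bladderRadiusMm,rectumRadiusMm,rectumLengthMm
#'   baseline organ dimensions, mm.
#' @param prostateCenter,bladderCenter,rectumCenter organ centres, mm.
#' @param bodySemiAxesMm,bodyZRangeMm body elliptic cylinder (x/y semi-axes
#'   and inferior/superior z limits).
#' @param marginMm margin of the dose plateau's target surrogate, default 10.
#' @param plateauShoulderMm distance beyond the prostate+margin surface at
#'   which the dose has fallen to 50\%, default 15 (keeps the whole baseline
#'   prostate on the plateau).
#' @param falloffMm logistic falloff scale of the dose edge, default 5.
#' @param bladderCv,rectumCv,prostateCv,bodyCv volume CV targets (fractions,
#'   not percent).
#' @param prostateDispSdMm per-axis SD of the anatomical prostate
#'   displacement, mm.
#' @param setupSdMm per-axis SD of the daily rigid setup error, mm.
#' @param bladderDriftMm superior bladder drift per unit volume-factor excess
#'   (filling pushes the bladder away from the prostate), default 10.
#' @param contourVertices vertices per emitted contour, default 64.
#' @return a validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(seed = 1L, nFractions = 20L, planDoseGy = 60,
                          doseSpacingMm = c(2, 2, 2),
                          ctSpacingMm = c(1, 1, 3),
                          prostateCenter = c(0, 0, 0),
                          prostateSemiAxesMm = c(25, 22, 18.3),
                          bladderCenter = c(0, -25, 55),
                          bladderRadiusMm = 36.63,
                          rectumCenter = c(0, 40, -5),
                          rectumRadiusMm = 15, rectumLengthMm = 104,
                          bodySemiAxesMm = c(85, 80),
                          bodyZRangeMm = c(-75, 110),
                          marginMm = 10, plateauShoulderMm = 15,
                          falloffMm = 5,
                          bladderCv = 0.352, rectumCv = 0.206,
                          prostateCv = 0.095, bodyCv = 0.02,
                          prostateDispSdMm = 2.10, setupSdMm = 3,
                          bladderDriftMm = 10, contourVertices = 64L) {
  cfg <- list(seed = as.integer(seed), nFractions = as.integer(nFractions),
              planDoseGy = planDoseGy, doseSpacingMm = doseSpacingMm,
              ctSpacingMm = ctSpacingMm, prostateCenter = prostateCenter,
              prostateSemiAxesMm = prostateSemiAxesMm,
              bladderCenter = bladderCenter,
              bladderRadiusMm = bladderRadiusMm,
              rectumCenter = rectumCenter, rectumRadiusMm = rectumRadiusMm,
              rectumLengthMm = rectumLengthMm,
              bodySemiAxesMm = bodySemiAxesMm, bodyZRangeMm = bodyZRangeMm,
              marginMm = marginMm, plateauShoulderMm = plateauShoulderMm,
              falloffMm = falloffMm, bladderCv = bladderCv,
              rectumCv = rectumCv, prostateCv = prostateCv, bodyCv = bodyCv,
              prostateDispSdMm = prostateDispSdMm, setupSdMm = setupSdMm,
              bladderDriftMm = bladderDriftMm,
              contourVertices = as.integer(contourVertices))
  class(cfg) <- "PhantomConfig"
  .validate_phantom_config(cfg)
  cfg
}

.validate_phantom_config <- function(cfg) {
  pos <- c("planDoseGy", "bladderRadiusMm", "rectumRadiusMm",
           "rectumLengthMm", "marginMm", "plateauShoulderMm", "falloffMm")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("phantom config: field '", f, "' must be positive")
  for (f in c("prostateSemiAxesMm", "bodySemiAxesMm", "doseSpacingMm",
              "ctSpacingMm"))
    if (any(cfg[[f]] <= 0)) stop("phantom config: field '", f,
                                 "' must be positive")
  for (f in c("bladderCv", "rectumCv", "prostateCv", "bodyCv",
              "prostateDispSdMm", "setupSdMm"))
    if (cfg[[f]] < 0) stop("phantom config: field '", f,
                           "' must be non-negative")
  if (cfg$nFractions < 1L) stop("phantom config: field 'nFractions' must be >= 1")
  shapes <- .baseline_shapes(cfg)
  # pairwise non-overlap of the organs at baseline (surface-point check)
  organs <- c("bladder", "rectum", "prostate")
  for (i in seq_along(organs)) for (j in seq_along(organs)) {
    if (i == j) next
    pts <- .shape_surface_points(shapes[[organs[i]]], 300L)
    if (any(.shape_inside(shapes[[organs[j]]], pts)))
      stop("phantom config: organs '", organs[i], "' and '", organs[j],
           "' overlap at baseline")
  }
  # prostate must sit on the dose plateau
  surf <- .shape_surface_points(shapes$prostate, 300L)
  if (min(.phantom_dose_at(cfg, surf)) < 0.98 * cfg$planDoseGy)
    stop("phantom config: baseline prostate extends off the dose plateau")
  invisible(cfg)
}

# --- analytic shapes -------------------------------------------------------

.baseline_shapes <- function(cfg) {
  list(
    body = list(type = "ellcyl",
                center = c(0, 0, mean(cfg$bodyZRangeMm)),
                semiAxes = cfg$bodySemiAxesMm,
                halfLength = diff(cfg$bodyZRangeMm) / 2),
    bladder = list(type = "ellipsoid", center = cfg$bladderCenter,
                   semiAxes = rep(cfg$bladderRadiusMm, 3)),
    rectum = list(type = "cylinder", center = cfg$rectumCenter,
                  radius = cfg$rectumRadiusMm,
                  halfLength = cfg$rectumLengthMm / 2),
    prostate = list(type = "ellipsoid", center = cfg$prostateCenter,
                    semiAxes = cfg$prostateSemiAxesMm))
}

.shape_inside <- function(shape, pts) {
  q <- sweep(pts, 2, shape$center)
  switch(shape$type,
    ellipsoid = rowSums(sweep(q, 2, shape$semiAxes, "/")^2) <= 1,
    cylinder = (q[, 1]^2 + q[, 2]^2 <= shape$radius^2) &
      abs(q[, 3]) <= shape$halfLength,
    ellcyl = ((q[, 1] / shape$semiAxes[1])^2 +
                (q[, 2] / shape$semiAxes[2])^2 <= 1) &
      abs(q[, 3]) <= shape$halfLength,
    ellipsoid_margin = .inside_ellipsoid_margin(shape, q),
    stop("unknown shape type: ", shape$type))
}

# inside the Minkowski sum of an ellipsoid with a ball of radius margin:
# inside the ellipsoid, or Euclidean distance to its surface <= margin.
# The distance uses the Lagrange closest-point equation
#   sum_i (a_i q_i / (t + a_i^2))^2 = 1, t > 0,
# solved by vectorized Newton iteration.
.inside_ellipsoid_margin <- function(shape, q) {
  a <- shape$semiAxes
  u2 <- rowSums(sweep(q, 2, a, "/")^2)
  inside <- u2 <= 1
  out <- which(!inside)
  if (!length(out)) return(inside)
  qo <- abs(q[out, , drop = FALSE])
  t <- sqrt(rowSums(qo^2)) * max(a)
  for (it in 1:40) {
    f <- rep(-1, length(t)); fp <- rep(0, length(t))
    for (i in 1:3) {
      w <- a[i] * qo[, i] / (t + a[i]^2)
      f <- f + w^2
      fp <- fp - 2 * w^2 / (t + a[i]^2)
    }
    step <- f / fp
    t <- pmax(t - step, 0)
    if (max(abs(step)) < 1e-10) break
  }
  d2 <- rep(0, length(t))
  for (i in 1:3) {
    xi <- a[i]^2 * qo[, i] / (t + a[i]^2)
    d2 <- d2 + (qo[, i] - xi)^2
  }
  inside[out] <- d2 <= shape$margin^2
  inside
}

.shape_volume <- function(shape) {
  switch(shape$type,
    ellipsoid = 4 / 3 * pi * prod(shape$semiAxes),
    cylinder = pi * shape$radius^2 * 2 * shape$halfLength,
    ellcyl = pi * prod(shape$semiAxes) * 2 * shape$halfLength,
    NA_real_)
}

.shape_bbox <- function(shape) {
  ext <- switch(shape$type,
    ellipsoid = shape$semiAxes,
    cylinder = c(shape$radius, shape$radius, shape$halfLength),
    ellcyl = c(shape$semiAxes, shape$halfLength),
    ellipsoid_margin = shape$semiAxes + shape$margin,
    stop("unknown shape type: ", shape$type))
  list(lo = shape$center - ext, hi = shape$center + ext)
}

.shape_surface_points <- function(shape, n) {
  # deterministic quasi-uniform surface sample (spherical Fibonacci lattice)
  i <- seq_len(n) - 0.5
  zu <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  dir <- cbind(sqrt(1 - zu^2) * cos(th), sqrt(1 - zu^2) * sin(th), zu)
  p <- switch(shape$type,
    ellipsoid = sweep(dir, 2, shape$semiAxes, "*"),
    cylinder = {
      r <- sqrt(dir[, 1]^2 + dir[, 2]^2)
      r[r < 1e-12] <- 1e-12
      cbind(dir[, 1] / r * shape$radius, dir[, 2] / r * shape$radius,
            sign(dir[, 3]) * shape$halfLength * abs(dir[, 3]))
    },
    ellcyl = {
      r <- sqrt(dir[, 1]^2 + dir[, 2]^2)
      r[r < 1e-12] <- 1e-12
      cbind(dir[, 1] / r * shape$semiAxes[1],
            dir[, 2] / r * shape$semiAxes[2],
            sign(dir[, 3]) * shape$halfLength * abs(dir[, 3]))
    },
    stop("unsupported shape for surface sampling: ", shape$type))
  sweep(p, 2, shape$center, "+")
}

# isotropic scale s about the shape centre, then translate by shift
.shape_rescale <- function(shape, s = 1, shift = c(0, 0, 0)) {
  shape$center <- shape$center + shift
  if (!is.null(shape$semiAxes)) shape$semiAxes <- shape$semiAxes * s
  if (!is.null(shape$radius)) shape$radius <- shape$radius * s
  if (!is.null(shape$halfLength)) shape$halfLength <- shape$halfLength * s
  shape
}

.shape_contours <- function(shape, zs, nv = 64L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  slices <- list()
  for (z in zs) {
    dz <- z - shape$center[3]
    ab <- switch(shape$type,
      ellipsoid = {
        f <- 1 - (dz / shape$semiAxes[3])^2
        if (f <= 1e-6) NULL else shape$semiAxes[1:2] * sqrt(f)
      },
      cylinder = if (abs(dz) <= shape$halfLength)
        rep(shape$radius, 2) else NULL,
      ellcyl = if (abs(dz) <= shape$halfLength) shape$semiAxes else NULL,
      stop("unsupported shape for contouring: ", shape$type))
    if (is.null(ab) || any(ab < 0.1)) next
    poly <- cbind(shape$center[1] + ab[1] * cos(th),
                  shape$center[2] + ab[2] * sin(th))
    slices[[length(slices) + 1L]] <- list(z = z, polygons = list(poly))
  }
  slices
}

# --- dose model ------------------------------------------------------------

# logistic plateau over prostate + margin: ellipsoidal radial coordinate u
# relative to the (prostate + margin) surface; 50% dose at u corresponding to
# plateauShoulderMm beyond it, falloff scale falloffMm.
.phantom_dose_at <- function(cfg, pts) {
  A <- cfg$prostateSemiAxesMm + cfg$marginMm
  rbar <- mean(A)
  u <- sqrt(rowSums(sweep(sweep(pts, 2, cfg$prostateCenter), 2, A, "/")^2))
  u50 <- 1 + cfg$plateauShoulderMm / rbar
  su <- cfg$falloffMm / rbar
  cfg$planDoseGy * stats::plogis((u50 - u) / su)
}

.phantom_dose_grid <- function(cfg, frameOfRef) {
  pad <- 2
  lo <- c(-cfg$bodySemiAxesMm[1], -cfg$bodySemiAxesMm[2],
          cfg$bodyZRangeMm[1]) - pad
  hi <- c(cfg$bodySemiAxesMm[1], cfg$bodySemiAxesMm[2],
          cfg$bodyZRangeMm[2]) + pad
  sp <- cfg$doseSpacingMm
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  geom <- ImageGeometry(lo, sp, dims, frameOfRef = frameOfRef)
  A <- cfg$prostateSemiAxesMm + cfg$marginMm
  ux <- ((.axis_coords(geom, 1) - cfg$prostateCenter[1]) / A[1])^2
  uy <- ((.axis_coords(geom, 2) - cfg$prostateCenter[2]) / A[2])^2
  uz <- ((.axis_coords(geom, 3) - cfg$prostateCenter[3]) / A[3])^2
  u <- sqrt(outer(outer(ux, uy, "+"), uz, "+"))
  rbar <- mean(A)
  vals <- cfg$planDoseGy *
    stats::plogis((1 + cfg$plateauShoulderMm / rbar - u) * rbar / cfg$falloffMm)
  DoseGrid(geom, vals)
}

.ct_geometry <- function(cfg, frameOfRef) {
  pad <- 2
  lo <- c(-cfg$bodySemiAxesMm[1], -cfg$bodySemiAxesMm[2],
          cfg$bodyZRangeMm[1]) - pad
  hi <- c(cfg$bodySemiAxesMm[1], cfg$bodySemiAxesMm[2],
          cfg$bodyZRangeMm[2]) + pad
  sp <- cfg$ctSpacingMm
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  ImageGeometry(lo, sp, dims, frameOfRef = frameOfRef)
}

.organ_colors <- list(body = c(0, 255, 0), bladder = c(0, 0, 255),
                      rectum = c(139, 69, 19), prostate = c(255, 0, 0))

.shapes_to_structures <- function(shapes, zs, nv, frameOfRef, sourceImageId) {
  rois <- mapply(function(shape, nm) {
    Roi(nm, .shape_contours(shape, zs, nv), color = .organ_colors[[nm]])
  }, shapes, names(shapes), SIMPLIFY = FALSE)
  StructureSet(rois, frameOfRef = frameOfRef, sourceImageId = sourceImageId)
}

.fx_seed <- function(seed, index)
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629)

# --- generators ------------------------------------------------------------

#' Generate the planning data of a phantom course
#'
#' Produces the planning structure set (analytic contours at the CT slice
#' positions), the plan dose grid (plateau with sigmoidal falloff), a minimal
#' CT geometry descriptor, and the analytic ground-truth shapes.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @return list with elements \code{structures} (\linkS4class{StructureSet}),
#'   \code{dose} (\linkS4class{DoseGrid}), \code{ctGeometry}
#'   (\linkS4class{ImageGeometry}), \code{shapes} (named list of analytic
#'   shapes), \code{frameOfRef}.
#' @export
generatePlanningSet <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  fr <- sprintf("FOR-PLAN-%d", cfg$seed)
  shapes <- .baseline_shapes(cfg)
  ct <- .ct_geometry(cfg, fr)
  ss <- .shapes_to_structures(shapes, .axis_coords(ct, 3),
                              cfg$contourVertices, fr,
                              sprintf("CT-PLAN-%d", cfg$seed))
  list(structures = ss, dose = .phantom_dose_grid(cfg, fr), ctGeometry = ct,
       shapes = shapes, frameOfRef = fr)
}

.lognorm_factor <- function(cv) {
  if (cv <= 0) return(1)
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(1, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate one daily fraction of a phantom course
#'
#' Draws the fraction's anatomy (seeded by \code{cfg$seed} and the fraction
#' index): organ volumes scaled by lognormal factors calibrated to the
#' per-organ CV targets (isotropic scaling about the organ centre; the
#' bladder additionally drifts superiorly with filling), the prostate centre
#' displaced by a 3-D Gaussian, and a rigid setup error applied to all
#' emitted structures and recorded inversely in the registration matrix.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @param index 1-based fraction index.
#' @param planning optional result of \code{\link{generatePlanningSet}} (to
#'   avoid recomputation).
#' @return list with \code{structures} (daily \linkS4class{StructureSet} in
#'   the daily frame), \code{registration}
#'   (\linkS4class{RegistrationMatrix}, daily to planning), and
#'   \code{groundTruth} (anatomy-frame shapes, true volumes in cm3, the
#'   prostate displacement, the setup error, and the volume factors).
#' @export
generateFraction <- function(cfg, index, planning = NULL) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  if (is.null(planning)) planning <- generatePlanningSet(cfg)
  set.seed(.fx_seed(cfg$seed, index))
  f_body <- .lognorm_factor(cfg$bodyCv)
  f_blad <- .lognorm_factor(cfg$bladderCv)
  f_rect <- .lognorm_factor(cfg$rectumCv)
  f_pros <- .lognorm_factor(cfg$prostateCv)
  disp <- stats::rnorm(3, 0, cfg$prostateDispSdMm)
  setup <- stats::rnorm(3, 0, cfg$setupSdMm)

  base <- planning$shapes
  anat <- list(
    body = .shape_rescale(base$body, f_body^(1 / 3)),
    bladder = .shape_rescale(base$bladder, f_blad^(1 / 3),
                             shift = c(0, 0, cfg$bladderDriftMm *
                                         (f_blad - 1))),
    rectum = .shape_rescale(base$rectum, f_rect^(1 / 3)),
    prostate = .shape_rescale(base$prostate, f_pros^(1 / 3), shift = disp))
  daily <- lapply(anat, .shape_rescale, s = 1, shift = setup)

  fr_daily <- sprintf("FOR-FX-%d-%d", cfg$seed, index)
  ct <- planning$ctGeometry
  ss <- .shapes_to_structures(daily, .axis_coords(ct, 3) + setup[3],
                              cfg$contourVertices, fr_daily,
                              sprintf("CBCT-%d-%d", cfg$seed, index))
  M <- diag(4)
  M[1:3, 4] <- -setup
  reg <- RegistrationMatrix(M, movingFrameId = fr_daily,
                            fixedFrameId = planning$frameOfRef)
  gt <- list(shapes = anat,
             volumes = vapply(anat, .shape_volume, numeric(1)) / 1000,
             factors = c(body = f_body, bladder = f_blad, rectum = f_rect,
                         prostate = f_pros),
             displacement = disp, setup = setup)
  list(structures = ss, registration = reg, groundTruth = gt)
}

#' Generate a phantom course in memory
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @return list with \code{course} (a \linkS4class{TreatmentCourse}) and
#'   \code{groundTruth} (planning shapes plus one ground-truth record per
#'   fraction).
#' @export
simulateCourse <- function(cfg) {
  planning <- generatePlanningSet(cfg)
  fx <- lapply(seq_len(cfg$nFractions), function(i)
    generateFraction(cfg, i, planning))
  records <- lapply(seq_along(fx), function(i)
    FractionRecord(i, fx[[i]]$structures, fx[[i]]$registration))
  course <- TreatmentCourse(planning$structures, planning$dose, records,
                            nFractionsPlanned = cfg$nFractions,
                            matrixMaps = "moving_to_fixed")
  list(course = course,
       groundTruth = list(planning = planning$shapes,
                          fractions = lapply(fx, `[[`, "groundTruth")))
}

#' Ground truth as a data frame
#'
#' One row per fraction and organ: the true (anatomy-frame) centre, volume,
#' volume factor, prostate displacement and setup error.
#'
#' @param gt the \code{groundTruth} element of \code{\link{simulateCourse}}.
#' @return a data.frame.
#' @export
groundTruthTable <- function(gt) {
  rows <- list()
  for (i in seq_along(gt$fractions)) {
    g <- gt$fractions[[i]]
    for (org in names(g$shapes)) {
      sh <- g$shapes[[org]]
      disp <- if (org == "prostate") g$displacement else c(0, 0, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = i, organ = org, volume_cm3 = g$volumes[[org]],
        volume_factor = g$factors[[org]],
        com_x = sh$center[1], com_y = sh$center[2], com_z = sh$center[3],
        disp_x = disp[1], disp_y = disp[2], disp_z = disp[3],
        disp_mm = sqrt(sum(disp^2)),
        setup_x = g$setup[1], setup_y = g$setup[2], setup_z = g$setup[3])
    }
  }
  do.call(rbind, rows)
}

#' Write a phantom course to disk
#'
#' Emits a loadable course: planning structures and dose (JSON), a CT
#' geometry descriptor, per-fraction structure sets and 4x4 text registration
#' matrices, a YAML manifest, and the ground-truth CSV.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly; the ground truth is returned as the
#'   attribute \code{"groundTruth"}.
#' @export
generateCourse <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCourse(cfg)
  course <- sim$course
  writeStructureSet(course@planningStructures,
                    file.path(dir, "planning_structures.json"))
  writeDoseGrid(course@planDose, file.path(dir, "plan_dose.json"))
  ctg <- .ct_geometry(cfg, course@planDose@geometry@frameOfRef)
  jsonlite::write_json(list(type = "doseacc.ct_geometry",
                            frame_of_reference = ctg@frameOfRef,
                            origin = ctg@origin, spacing = ctg@spacing,
                            dims = ctg@dims, hu_body = 0, hu_prostate = 40,
                            hu_bladder = 30, hu_rectum = -50),
                       file.path(dir, "planning_ct.json"),
                       auto_unbox = TRUE, digits = NA)
  fx_entries <- list()
  for (f in course@fractions) {
    sfile <- sprintf("fx%03d_structures.json", f@index)
    rfile <- sprintf("fx%03d_registration.txt", f@index)
    writeStructureSet(f@structures, file.path(dir, sfile))
    writeRegistration(f@registration, file.path(dir, rfile))
    fx_entries[[length(fx_entries) + 1L]] <-
      list(index = f@index, structures = sfile, registration = rfile,
           label = f@label)
  }
  manifest <- list(type = "doseacc.course",
                   n_fractions_planned = cfg$nFractions,
                   matrix_maps = "moving_to_fixed",
                   planning = list(structures = "planning_structures.json",
                                   dose = "plan_dose.json",
                                   ct = "planning_ct.json"),
                   fractions = fx_entries)
  mpath <- file.path(dir, "course.yaml")
  yaml::write_yaml(manifest, mpath)
  utils::write.csv(groundTruthTable(sim$groundTruth),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  structure(invisible(mpath), groundTruth = sim$groundTruth)
}
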