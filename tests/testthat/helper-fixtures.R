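# Fixtures are built in code: analytic contour stacks, uniform dose grids,
# a down-scaled phantom for fast integration tests, and a two-region cube
# course for accumulation arithmetic.

circle_poly <- function(r, center = c(0, 0), nv = 64L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

sphere_roi <- function(r, center = c(0, 0, 0), dz = 1, nv = 64L,
                       name = "sphere") {
  zs <- seq(center[3] - r, center[3] + r, by = dz)
  slices <- list()
  for (z in zs) {
    f <- r^2 - (z - center[3])^2
    if (f <= 1e-9) next
    slices[[length(slices) + 1L]] <-
      list(z = z, polygons = list(circle_poly(sqrt(f), center[1:2], nv)))
  }
  Roi(name, slices)
}

square_poly <- function(side, center = c(0, 0)) {
  h <- side / 2
  cbind(center[1] + c(-h, h, h, -h), center[2] + c(-h, -h, h, h))
}

cube_roi <- function(side, center = c(0, 0, 0), dz = 1, name = "cube") {
  zs <- seq(center[3] - side / 2, center[3] + side / 2, by = dz)
  slices <- lapply(zs, function(z)
    list(z = z, polygons = list(square_poly(side, center[1:2]))))
  Roi(name, slices)
}

unit_geom <- function(dims = c(51, 51, 51), origin = c(-25, -25, -25),
                      spacing = c(1, 1, 1), frame = "FOR-T")
  ImageGeometry(origin, spacing, dims, frameOfRef = frame)

uniform_dose <- function(valueGy = 60, geom = unit_geom())
  DoseGrid(geom, array(valueGy, geom@dims))

# down-scaled pelvic phantom (about 8x fewer voxels than the default) for
# integration tests that do not probe the default study conditions
mini_phantom_cfg <- function(...) {
  args <- utils::modifyList(
    list(bodySemiAxesMm = c(40, 40), bodyZRangeMm = c(-40, 50),
         bladderCenter = c(0, -15, 32), bladderRadiusMm = 20,
         rectumCenter = c(0, 25, -3), rectumRadiusMm = 8,
         rectumLengthMm = 50, prostateSemiAxesMm = c(12, 10, 9)),
    list(...))
  do.call(phantomConfig, args)
}

# course with a two-level dose field (40 Gy for x below the midline, 60 Gy
# above) and a cube structure that each fraction places in one region
two_region_course <- function(fraction_centers,
                              baseline_center = c(10, 10, 10)) {
  geom <- ImageGeometry(c(1, 1, 1), c(1, 1, 1), c(40L, 20L, 20L),
                        frameOfRef = "FOR-2R")
  vals <- array(40, geom@dims)
  vals[21:40, , ] <- 60
  dose <- DoseGrid(geom, vals)
  plan <- StructureSet(list(cube = cube_roi(8, baseline_center)),
                       frameOfRef = "FOR-2R")
  fx <- lapply(seq_along(fraction_centers), function(i)
    FractionRecord(i, StructureSet(list(cube =
      cube_roi(8, fraction_centers[[i]])), frameOfRef = "FOR-2R"),
      RegistrationMatrix(diag(4))))
  TreatmentCourse(plan, dose, fx)
}

cube_config <- function(...)
  courseConfig(structures = "cube", marginMm = 0, ...)
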