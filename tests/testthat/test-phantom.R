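test_that("phantom configuration is validated", {
  expect_error(mini_phantom_cfg(bladderRadiusMm = -5), "positive")
  expect_error(mini_phantom_cfg(nFractions = 0), "nFractions")
  # bladder placed on top of the prostate overlaps at baseline
  expect_error(mini_phantom_cfg(bladderCenter = c(0, 0, 5)), "overlap")
  # a dose edge pulled inside the prostate surface is rejected
  expect_error(mini_phantom_cfg(marginMm = 1, plateauShoulderMm = 0.5,
                                falloffMm = 2), "plateau")
})

test_that("the planning set realizes the dose model", {
  cfg <- mini_phantom_cfg(seed = 2, nFractions = 1)
  pl <- generatePlanningSet(cfg)
  expect_setequal(roiNames(pl$structures),
                  c("body", "bladder", "rectum", "prostate"))
  # analytic volumes: contoured organs rasterize close to the closed forms
  geom <- resampleGeometry(pl$dose@geometry, c(1, 1, 1))
  for (org in c("bladder", "prostate")) {
    v <- maskVolume(rasterizeRoi(getRoi(pl$structures, org), geom))
    expect_lt(abs(v * 1000 / doseacc:::.shape_volume(pl$shapes[[org]]) - 1),
              0.03)
  }
  # prostate sits on the plateau; organs at distance are colder
  ps <- sampleDose(rasterizeRoi(getRoi(pl$structures, "prostate"), geom),
                   pl$dose)
  bs <- sampleDose(rasterizeRoi(getRoi(pl$structures, "bladder"), geom),
                   pl$dose)
  expect_lt(abs(meanDose(ps) / cfg$planDoseGy - 1), 0.01)
  expect_lt(meanDose(bs), meanDose(ps))
})

test_that("zero variability reproduces the planning anatomy exactly", {
  cfg <- mini_phantom_cfg(seed = 5, nFractions = 2, bladderCv = 0,
                          rectumCv = 0, prostateCv = 0, bodyCv = 0,
                          prostateDispSdMm = 0, setupSdMm = 0)
  pl <- generatePlanningSet(cfg)
  fx <- generateFraction(cfg, 1, pl)
  expect_equal(fx$registration@matrix, diag(4))
  for (nm in roiNames(pl$structures))
    expect_equal(getRoi(fx$structures, nm)@slices,
                 getRoi(pl$structures, nm)@slices)
  expect_equal(fx$groundTruth$displacement, c(0, 0, 0))
})

test_that("the registration corrects exactly the setup error", {
  cfg <- mini_phantom_cfg(seed = 6, nFractions = 1, bladderCv = 0,
                          rectumCv = 0, prostateCv = 0, bodyCv = 0,
                          prostateDispSdMm = 0, setupSdMm = 4)
  pl <- generatePlanningSet(cfg)
  fx <- generateFraction(cfg, 1, pl)
  expect_gt(max(abs(fx$groundTruth$setup)), 0)
  expect_equal(fx$registration@matrix[1:3, 4], -fx$groundTruth$setup)
  geom <- resampleGeometry(pl$dose@geometry, c(1, 1, 1))
  base <- rasterizeRoi(getRoi(pl$structures, "prostate"), geom)
  daily <- rasterizeRoi(transformRoi(getRoi(fx$structures, "prostate"),
                                     fx$registration), geom)
  expect_lt(centerOfMassDistance(daily, base), 0.5)
})

test_that("lognormal volume factors hit the requested CV", {
  # CV of a lognormal with sigma^2 = log(1 + cv^2) is cv by construction
  set.seed(31)
  f <- replicate(200, doseacc:::.lognorm_factor(0.35))
  expect_lt(abs(mean(f) - 1), 3 * 0.35 / sqrt(200))
  expect_lt(abs(coefficientOfVariation(f) - 35), 5)
  expect_identical(doseacc:::.lognorm_factor(0), 1)
})

test_that("courses are deterministic in the seed", {
  cfg <- mini_phantom_cfg(seed = 17, nFractions = 2)
  d1 <- tempfile("c1"); d2 <- tempfile("c2"); d3 <- tempfile("c3")
  generateCourse(cfg, d1)
  generateCourse(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  generateCourse(mini_phantom_cfg(seed = 18, nFractions = 2), d3)
  expect_false(identical(readLines(file.path(d1, "ground_truth.csv")),
                         readLines(file.path(d3, "ground_truth.csv"))))
})

test_that("generated courses round-trip through the course loader", {
  cfg <- mini_phantom_cfg(seed = 23, nFractions = 2)
  dir <- tempfile("course")
  generateCourse(cfg, dir)
  course <- loadCourse(file.path(dir, "course.yaml"))
  sim <- simulateCourse(cfg)
  expect_identical(nFractions(course), 2L)
  # loaded contours match the in-memory course within the writer precision
  for (i in 1:2) {
    a <- getRoi(course@fractions[[i]]@structures, "prostate")
    b <- getRoi(sim$course@fractions[[i]]@structures, "prostate")
    expect_lt(max(abs(a@slices[[3]]$polygons[[1]] -
                        b@slices[[3]]$polygons[[1]])), 1e-3)
    expect_lt(max(abs(course@fractions[[i]]@registration@matrix -
                        sim$course@fractions[[i]]@registration@matrix)),
              1e-9)
  }
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_identical(nrow(gt), 8L)  # 2 fractions x 4 organs
  expect_setequal(unique(gt$organ), c("body", "bladder", "rectum",
                                      "prostate"))
})

test_that("the analytic oracle is exact on uniform fields and converges", {
  geom <- unit_geom(c(21L, 21L, 21L), c(-10, -10, -10))
  dose <- uniform_dose(55, geom)
  shape <- list(type = "ellipsoid", center = c(0, 0, 0),
                semiAxes = c(6, 5, 4))
  m <- oracleMetrics(shape, dose, 2e4, seed = 1)
  expect_equal(unname(m["Dmean_Gy"]), 55)
  expect_equal(unname(m["V20Gy_pct"]), 100)

  cfg <- mini_phantom_cfg(seed = 2, nFractions = 1)
  pl <- generatePlanningSet(cfg)
  m1 <- oracleMetrics(pl$shapes$prostate, pl$dose, 5e4, seed = 7)
  m2 <- oracleMetrics(pl$shapes$prostate, pl$dose, 1e5, seed = 8)
  # doubling the point count moves the metrics by less than 0.2%
  expect_lt(max(abs(m2 - m1) / pmax(abs(m2), 1)), 0.002)
  # oracle vs voxel pipeline on the baseline prostate within 1%
  geomr <- resampleGeometry(pl$dose@geometry, c(1, 1, 1))
  smp <- sampleDose(rasterizeRoi(getRoi(pl$structures, "prostate"), geomr),
                    pl$dose)
  expect_lt(abs(meanDose(smp) / m2[["Dmean_Gy"]] - 1), 0.01)
})

test_that("the margin shape matches voxel margin expansion", {
  cfg <- mini_phantom_cfg(seed = 2, nFractions = 1)
  pl <- generatePlanningSet(cfg)
  geom <- resampleGeometry(pl$dose@geometry, c(1, 1, 1))
  vox <- expandMargin(rasterizeRoi(getRoi(pl$structures, "prostate"), geom),
                      10)
  sh <- marginShape(pl$shapes$prostate, 10)
  # compare the margin volume against rejection-sampled inside fraction
  bb <- doseacc:::.shape_bbox(sh)
  set.seed(12)
  pts <- cbind(runif(2e5, bb$lo[1], bb$hi[1]),
               runif(2e5, bb$lo[2], bb$hi[2]),
               runif(2e5, bb$lo[3], bb$hi[3]))
  frac <- mean(doseacc:::.shape_inside(sh, pts))
  vol_mc <- frac * prod(bb$hi - bb$lo) / 1000
  expect_lt(abs(maskVolume(vox) / vol_mc - 1), 0.03)
})
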