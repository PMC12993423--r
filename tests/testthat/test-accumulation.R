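# two-region course: baseline cube in the 40 Gy region; helper fixtures in
# helper-fixtures.R

test_that("an identity course reproduces the baseline exactly", {
  course <- two_region_course(list(c(10, 10, 10), c(10, 10, 10)))
  rep <- runCourse(course, cube_config())
  expect_length(rep@fractionResults, 2L)
  devs <- unlist(rep@accumulated@deviationPct)
  expect_true(all(abs(devs) == 0, na.rm = TRUE))
  expect_false(any(unlist(rep@accumulated@flags)))
  b <- rep@baseline@curves$cube
  a <- rep@accumulated@curves$cube
  expect_equal(a@cumVolumePct[seq_along(b@cumVolumePct)], b@cumVolumePct)
  fx <- rep@fractionResults[[1]]
  expect_equal(fx@geometry$cube$dsc, 1)
  expect_equal(fx@geometry$cube$cmd_mm, 0)
  expect_equal(fx@geometry$cube$volume_dev_pct, 0)
})

test_that("two uniform fractions at 40 and 60 Gy average as expected", {
  course <- two_region_course(list(c(10, 10, 10), c(30, 10, 10)))
  rep <- runCourse(course, cube_config())
  m1 <- rep@fractionResults[[1]]@metrics$cube
  m2 <- rep@fractionResults[[2]]@metrics$cube
  expect_equal(unname(m1["Dmean_Gy"]), 40)
  expect_equal(unname(m2["Dmean_Gy"]), 60)
  acc <- rep@accumulated@metrics$cube
  expect_equal(unname(acc["V50Gy_pct"]), 50, tolerance = 1e-6)
  expect_equal(unname(acc["Dmean_Gy"]), 50, tolerance = 1e-2)
  # deviation vs the 40 Gy baseline: +25% mean dose, flagged at 2%
  expect_equal(unname(rep@accumulated@deviationPct$cube["Dmean_Gy"]), 25,
               tolerance = 1e-2)
  expect_true(rep@accumulated@flags$cube[["Dmean_Gy"]])
})

test_that("accumulation is invariant to fraction order and bin width checked", {
  course <- two_region_course(list(c(10, 10, 10), c(30, 10, 10),
                                   c(12, 10, 10)))
  cfg <- cube_config()
  bl <- evaluateBaseline(course, cfg)
  res <- lapply(course@fractions, function(f)
    evaluateFraction(course, f, bl, cfg))
  a1 <- accumulateFractions(res, bl, 3, cfg)
  a2 <- accumulateFractions(rev(res), bl, 3, cfg)
  expect_equal(a1@curves$cube@cumVolumePct, a2@curves$cube@cumVolumePct)
  expect_equal(a1@metrics, a2@metrics)
  # mixing bin widths is a configuration error
  res2 <- res
  res2[[2]]@curves$cube <- cumulativeDvh(
    doseacc:::.dose_samples(rep(60, 10)), 0.2)
  expect_error(accumulateFractions(res2, bl, 3, cfg), "bin width")
})

test_that("mean dose responds monotonically to drift out of the field", {
  course <- two_region_course(list(c(30, 10, 10), c(24, 10, 10),
                                   c(18, 10, 10), c(12, 10, 10)),
                              baseline_center = c(30, 10, 10))
  rep <- runCourse(course, cube_config())
  md <- vapply(rep@fractionResults, function(f)
    f@metrics$cube[["Dmean_Gy"]], numeric(1))
  expect_true(all(diff(md) < 0))
})

test_that("threshold exceedance rates count deviations correctly", {
  mk <- function(dev) new("FractionResult", index = 1L, geometry = list(),
                          metrics = list(),
                          deviations = list(bladder = c(Dmean_Gy = dev)),
                          curves = list())
  res <- lapply(c(1, 3, 5, 0.5), mk)
  expect_equal(thresholdExceedanceRate(res, "Dmean_Gy", "bladder", 2), 50)
  expect_equal(thresholdExceedanceRate(lapply(rep(0, 4), mk), "Dmean_Gy",
                                       "bladder", 2), 0)
  expect_equal(thresholdExceedanceRate(res, "Dmean_Gy", "bladder", 0), 100)
  expect_error(thresholdExceedanceRate(res, "D999_Gy", "bladder", 2),
               "unknown metric")
  expect_error(thresholdExceedanceRate(res, "Dmean_Gy", "femur", 2),
               "not present")
})

test_that("lenient mode records fraction failures, strict mode raises", {
  course <- two_region_course(list(c(10, 10, 10), c(30, 10, 10)))
  # fraction 2 lacks the requested structure
  broken <- course@fractions[[2]]
  broken@structures <- StructureSet(list(other = cube_roi(4, c(10, 10, 10),
                                                          name = "other")),
                                    frameOfRef = "FOR-2R")
  course@fractions[[2]] <- broken
  rep <- runCourse(course, cube_config())
  expect_length(rep@fractionResults, 1L)
  expect_named(rep@failures, "fraction_2")
  expect_match(rep@failures$fraction_2, "cube")
  expect_error(runCourse(course, cube_config(strict = TRUE)), "fraction 2")
})

test_that("missing structures are reported with the available names", {
  course <- two_region_course(list(c(10, 10, 10)))
  expect_error(evaluateBaseline(course, courseConfig(structures = "rectum",
                                                     marginMm = 0)),
               "available: cube")
})

test_that("the margin target is regenerated from the daily prostate", {
  cfg <- mini_phantom_cfg(seed = 9, nFractions = 1, bladderCv = 0,
                          rectumCv = 0, prostateCv = 0.4, bodyCv = 0,
                          prostateDispSdMm = 0, setupSdMm = 0)
  sim <- simulateCourse(cfg)
  run <- courseConfig()
  bl <- evaluateBaseline(sim$course, run)
  fr <- evaluateFraction(sim$course, sim$course@fractions[[1]], bl, run)
  expect_true("prostate+1cm" %in% names(fr@metrics))
  # margin volume exceeds the organ volume (dilation is extensive)
  expect_gt(bl@volumes[["prostate+1cm"]], bl@volumes[["prostate"]])
  # the daily margin follows the daily (rescaled) prostate, not the plan
  f <- sim$groundTruth$fractions[[1]]$factors[["prostate"]]
  expect_gt(abs(fr@geometry$`prostate+1cm`$volume_dev_pct), 0)
  expect_equal(sign(fr@geometry$`prostate+1cm`$volume_dev_pct),
               sign(f - 1))
})

test_that("a prostate pushed off the plateau edge loses near-minimum dose", {
  cfg <- mini_phantom_cfg(seed = 3, nFractions = 1, bladderCv = 0,
                          rectumCv = 0, prostateCv = 0, bodyCv = 0,
                          prostateDispSdMm = 0, setupSdMm = 0)
  sim <- simulateCourse(cfg)
  run <- courseConfig()
  bl <- evaluateBaseline(sim$course, run)
  fx <- sim$course@fractions[[1]]
  M <- diag(4); M[1:3, 4] <- c(12, 0, 0)  # push 12 mm towards the field edge
  fx@registration <- RegistrationMatrix(M)
  fr <- evaluateFraction(sim$course, fx, bl, run)
  expect_lt(fr@metrics$prostate[["D98_Gy"]], bl@metrics$prostate[["D98_Gy"]])
  expect_lt(fr@deviations$prostate[["D98_Gy"]], 0)
})
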