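test_that("rigid transforms move vertices exactly on the translation path", {
  roi <- sphere_roi(10, c(0, 0, 0))
  ident <- RegistrationMatrix(diag(4))
  same <- transformRoi(roi, ident)
  expect_equal(same@slices, roi@slices)

  M <- diag(4); M[1:3, 4] <- c(3, 0, 4)
  shifted <- transformRoi(roi, RegistrationMatrix(M))
  expect_equal(shifted@slices[[1]]$z, roi@slices[[1]]$z + 4)
  expect_equal(shifted@slices[[1]]$polygons[[1]],
               sweep(roi@slices[[1]]$polygons[[1]], 2, c(3, 0), "+"))

  # forward then inverse composition restores vertices to 1e-6 mm
  back <- transformRoi(shifted, RegistrationMatrix(M), "fixed_to_moving")
  for (i in seq_along(roi@slices))
    expect_lt(max(abs(back@slices[[i]]$polygons[[1]] -
                        roi@slices[[i]]$polygons[[1]])), 1e-6)
  expect_error(transformRoi(Roi("x", list()), ident), "empty structure")
})

test_that("small rotations preserve rasterized volume within 2%", {
  roi <- sphere_roi(15, c(2, -3, 1))
  geom <- unit_geom(c(61L, 61L, 61L), c(-30, -30, -30))
  v0 <- maskVolume(rasterizeRoi(roi, geom))
  th <- 3 * pi / 180
  M <- diag(4)
  M[1:3, 1:3] <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                       c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- transformRoi(roi, RegistrationMatrix(M))
  v1 <- maskVolume(rasterizeRoi(rot, geom))
  expect_lt(abs(v1 / v0 - 1), 0.02)
})

test_that("rasterization reproduces analytic areas and volumes", {
  # 20 mm cube on a 1 mm grid
  geom <- unit_geom(c(31L, 31L, 31L), c(-15, -15, -15))
  vc <- maskVolume(rasterizeRoi(cube_roi(20), geom)) * 1000
  expect_lt(abs(vc - 8000) / 8000, 0.06)
  # square with a concentric half-size hole: even-odd rule leaves 75%
  g2 <- ImageGeometry(c(-19.5, -19.5, 0), c(1, 1, 1), c(40L, 40L, 1L))
  roi <- Roi("holed", list(list(z = 0, polygons = list(square_poly(20),
                                                       square_poly(10)))))
  a <- sum(rasterizeRoi(roi, g2)@voxels)
  expect_lt(abs(a - 0.75 * 400) / 300, 0.05)
  # sphere r = 25 mm, 1 mm grid, supersample 2: within 1% of 65449.85 mm3
  g3 <- unit_geom(c(61L, 61L, 61L), c(-30, -30, -30))
  vs <- maskVolume(rasterizeRoi(sphere_roi(25), g3, 2L)) * 1000
  expect_lt(abs(vs - 65449.85) / 65449.85, 0.01)
})

test_that("rasterization converges as the grid is refined", {
  analytic <- 4 / 3 * pi * 10^3
  err <- vapply(c(2, 1), function(sp) {
    g <- ImageGeometry(c(-14, -14, -14), rep(sp, 3),
                       rep(as.integer(28 / sp) + 1L, 3))
    abs(maskVolume(rasterizeRoi(sphere_roi(10, dz = sp), g)) * 1000 -
          analytic) / analytic
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("contour planes outside the grid are dropped with a warning", {
  g <- ImageGeometry(c(-15, -15, 0), c(1, 1, 1), c(31L, 31L, 5L))
  roi <- sphere_roi(10, c(0, 0, 20))
  expect_warning(m <- rasterizeRoi(roi, g), "outside the grid")
  expect_identical(sum(m@voxels), 0L)
  roi2 <- sphere_roi(10, c(0, 0, 3))
  expect_warning(m2 <- rasterizeRoi(roi2, g), "out-of-range")
  expect_gt(sum(m2@voxels), 0L)
})

test_that("volume, centre of mass and CMD follow the analytic fixtures", {
  g <- unit_geom(c(21L, 21L, 21L), c(-10, -10, -10))
  empty <- BinaryMask(g, array(FALSE, g@dims), "empty")
  expect_identical(maskVolume(empty), 0)
  one <- array(FALSE, g@dims); one[11, 11, 11] <- TRUE
  m1 <- BinaryMask(g, one, "one")
  expect_equal(maskVolume(m1), 0.001)
  expect_equal(centerOfMass(m1), c(0, 0, 0))
  two <- one; two[13, 11, 11] <- TRUE
  expect_equal(centerOfMass(BinaryMask(g, two, "two")), c(1, 0, 0))
  expect_error(centerOfMass(empty), "empty structure")

  # 1000 voxels at 1 mm3 is exactly 1 cm3
  blk <- array(FALSE, g@dims); blk[1:10, 1:10, 1:10] <- TRUE
  expect_equal(maskVolume(BinaryMask(g, blk, "blk")), 1)

  # symmetric sphere: COM at centre within half a voxel
  gs <- ImageGeometry(c(-20, -50, 20), c(1, 1, 1), c(61L, 61L, 61L))
  ms <- rasterizeRoi(sphere_roi(12, c(10, -20, 50)), gs)
  expect_lt(max(abs(centerOfMass(ms) - c(10, -20, 50))), 0.5)

  # 3-4-5 triangle
  a <- array(FALSE, g@dims); a[5, 5, 5] <- TRUE
  b <- array(FALSE, g@dims); b[8, 9, 5] <- TRUE
  expect_equal(centerOfMassDistance(BinaryMask(g, a, "a"),
                                    BinaryMask(g, b, "b")), 5)
  expect_equal(centerOfMassDistance(BinaryMask(g, a, "a"),
                                    BinaryMask(g, a, "a")), 0)
})

test_that("CMD satisfies the triangle inequality", {
  g <- unit_geom(c(31L, 31L, 31L), c(-15, -15, -15))
  set.seed(9)
  mk <- function() {
    v <- array(FALSE, g@dims)
    v[sample(prod(g@dims), 50)] <- TRUE
    BinaryMask(g, v, "m")
  }
  for (rep in 1:5) {
    m1 <- mk(); m2 <- mk(); m3 <- mk()
    expect_lte(centerOfMassDistance(m1, m3),
               centerOfMassDistance(m1, m2) +
                 centerOfMassDistance(m2, m3) + 1e-9)
  }
})

test_that("Dice matches the sphere-overlap closed form and edge cases", {
  g <- ImageGeometry(c(-15, -15, -15), c(1, 1, 1), c(41L, 31L, 31L))
  a <- rasterizeRoi(sphere_roi(10, c(0, 0, 0)), g)
  b <- rasterizeRoi(sphere_roi(10, c(10, 0, 0)), g)
  expect_equal(diceCoefficient(a, a), 1)
  # equal spheres r, centres d apart: DSC = (4r + d)(2r - d)^2 / (16 r^3)
  expect_lt(abs(diceCoefficient(a, b) - 0.3125) / 0.3125, 0.02)
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  empty <- BinaryMask(g, array(FALSE, g@dims), "e")
  expect_identical(diceCoefficient(a, empty), 0)
  expect_error(diceCoefficient(empty, empty), "undefined")
  far <- rasterizeRoi(sphere_roi(3, c(-11, -11, -11)), g)
  expect_identical(diceCoefficient(a, far), 0)
})

test_that("margin expansion matches analytic balls and is monotone", {
  g <- unit_geom(c(31L, 31L, 31L), c(-15, -15, -15))
  one <- array(FALSE, g@dims); one[16, 16, 16] <- TRUE
  pt <- BinaryMask(g, one, "pt")
  ball <- expandMargin(pt, 10)
  expect_lt(abs(maskVolume(ball) * 1000 - 4188.79) / 4188.79, 0.05)
  # no growth possible below half the minimum spacing
  expect_identical(expandMargin(pt, 0.4)@voxels, pt@voxels)
  # monotone: larger margin is a superset
  small <- expandMargin(pt, 5)
  expect_true(all(ball@voxels[small@voxels]))
  expect_error(expandMargin(BinaryMask(g, array(FALSE, g@dims), "e"), 5),
               "empty structure")
  # sphere r=20 grown by 10 approximates sphere r=30
  g2 <- unit_geom(c(71L, 71L, 71L), c(-35, -35, -35))
  s20 <- rasterizeRoi(sphere_roi(20), g2)
  grown <- expandMargin(s20, 10)
  expect_lt(abs(maskVolume(grown) * 1000 - 4 / 3 * pi * 30^3) /
              (4 / 3 * pi * 30^3), 0.02)
})

test_that("anisotropic spacing is honoured by volume and margin", {
  g <- ImageGeometry(c(0, 0, 0), c(1, 1, 3), c(30L, 30L, 10L))
  v <- array(FALSE, g@dims); v[10:19, 10:19, 4:5] <- TRUE
  m <- BinaryMask(g, v, "slab")
  expect_equal(maskVolume(m), 10 * 10 * 2 * 3 / 1000)
  grown <- expandMargin(m, 3)
  # 3 mm reaches exactly one slice up and down but 3 voxels in-plane
  expect_true(any(grown@voxels[, , 3]) && any(grown@voxels[, , 6]))
  expect_false(any(grown@voxels[, , 2]) || any(grown@voxels[, , 7]))
  expect_true(grown@voxels[7, 15, 4])
  expect_false(grown@voxels[6, 15, 4])
})
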