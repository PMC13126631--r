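test_that("contact height matches forced geometric cases", {
  tip <- TipModel(radius = 1, halfAngle = 10)
  # on-axis contact: apex reaches z_bead + r
  expect_equal(contactHeight(2, 1, 0, tip), 3.0)
  # the two branch formulas agree at the crossover d = (R + r) cos(Theta)
  th <- 10 * pi / 180
  for (r in c(0.3, 0.8, 1.4)) {
    d0 <- (1 + r) * cos(th)
    cap <- 2 + sqrt((1 + r)^2 - d0^2) - 1
    flank <- 2 + (1 + r - d0 * cos(th)) / sin(th) - 1
    expect_lt(abs(cap - flank), 1e-12)
    # and the implementation is continuous across it
    expect_lt(abs(contactHeight(2, r, d0 - 1e-9, tip) -
                  contactHeight(2, r, d0 + 1e-9, tip)), 1e-7)
  }
})

test_that("contact height agrees with the discretized tip-lowering oracle", {
  set.seed(101)
  for (i in 1:25) {
    z <- runif(1, 0.5, 4); r <- runif(1, 0.2, 1.2); d <- runif(1, 0, 4)
    R <- runif(1, 1, 3); th <- runif(1, 5, 30)
    ana <- contactHeight(z, r, d, TipModel(R, th))
    ora <- oracleContactHeight(z, r, d, R, th)
    expect_lt(abs(ana - ora), 1e-3)
  }
})

test_that("pose transform follows the z-x-y extrinsic convention", {
  R <- afmstate:::.rotZXY(90, 0, 0)
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  # inverse composition restores coordinates
  set.seed(7)
  for (i in 1:10) {
    ang <- runif(3, -180, 180)
    M <- afmstate:::.rotZXY(ang[1], ang[2], ang[3])
    d <- pi / 180
    Rz <- afmstate:::.rotZXY(-ang[1], 0, 0)
    Rx <- afmstate:::.rotZXY(0, -ang[2], 0)
    Ry <- afmstate:::.rotZXY(0, 0, -ang[3])
    expect_equal(Rz %*% Rx %*% Ry %*% M, diag(3), tolerance = 1e-9)
  }
})

test_that("stage conventions rest the model on z = 0", {
  bm <- twoBeadModel()
  surf <- transformModel(bm, Pose())
  expect_equal(min(coords(surf)[, 3] - radii(surf)), 0)
  cent <- transformModel(bm, Pose(), stage = "center")
  expect_equal(min(coords(cent)[, 3]), 0)
  # identity pose only recenters laterally and shifts z
  expect_equal(diff(coords(surf)[, 1]), diff(coords(bm)[, 1]))
})

test_that("render equals the per-pixel contact-height maximum", {
  bm <- twoBeadModel()
  pose <- Pose(x = 0.4, y = -0.3, phi = 8, theta = -5, psi = 40)
  tip <- TipModel(1.2, 12)
  grid <- ImageGrid(14L, 11L, 0.6)
  img <- renderImage(bm, pose, tip, grid)
  posed <- transformModel(bm, pose)
  for (i in c(1L, 5L, 11L)) for (j in c(1L, 7L, 14L)) {
    px <- grid@origin + c(j - 0.5, i - 0.5) * grid@pixelSize
    d <- sqrt((coords(posed)[, 1] - px[1])^2 + (coords(posed)[, 2] - px[2])^2)
    h <- max(0, contactHeight(coords(posed)[, 3], radii(posed), d, tip))
    expect_equal(heights(img)[i, j], h, tolerance = 1e-12)
  }
})

test_that("sphere on the stage images at twice its radius", {
  bm <- BeadModel(rbind(c(0, 0, 99)), radii = 1, kinds = "ALA")
  # odd grid: one pixel center lies exactly on the bead axis
  img <- renderImage(bm, Pose(), TipModel(1, 10), ImageGrid(17L, 17L, 0.5))
  expect_equal(max(heights(img)), 2.0)
  # pixels far outside the dilated footprint are bare stage
  expect_equal(heights(img)[1L, 1L], 0)
  expect_true(all(heights(img) >= 0))
  expect_true(all(heights(img) <= 2.0 + 1e-12))
})

test_that("render is monotone under tip blunting (dilation property)", {
  set.seed(3)
  bm <- BeadModel(matrix(c(runif(12, -3, 3), runif(6, 0.5, 3)), 6L),
                  radii = runif(6, 0.3, 1), kinds = "ALA")
  grid <- ImageGrid(20L, 20L, 0.7)
  h0 <- heights(renderImage(bm, Pose(), TipModel(1.0, 10), grid))
  hR <- heights(renderImage(bm, Pose(), TipModel(2.5, 10), grid))
  hT <- heights(renderImage(bm, Pose(), TipModel(1.0, 25), grid))
  expect_true(all(hR >= h0 - 1e-12))
  expect_true(all(hT >= h0 - 1e-12))
})

test_that("whole-pixel model shifts translate the image", {
  bm <- twoBeadModel()
  grid <- ImageGrid(20L, 20L, 0.8)
  tip <- TipModel(1, 10)
  a <- heights(renderImage(bm, Pose(), tip, grid))
  b <- heights(renderImage(bm, Pose(x = 2 * 0.8), tip, grid))
  # interior columns shift by two pixels
  expect_equal(b[, 3:20], a[, 1:18], tolerance = 1e-10)
})

test_that("simulation parameters come from the printed grids", {
  ranges <- simParamRanges()
  expect_equal(ranges$R, seq(1, 3, by = 0.1))
  expect_equal(ranges$thetaTip, seq(5, 30, by = 1))
  expect_equal(range(ranges$phi), c(-20, 20))
  expect_equal(range(ranges$psi), c(-180, 180))
  set.seed(5)
  draws <- replicate(4000, {
    p <- sampleSimParams(ranges)
    c(p$tip@radius, p$tip@halfAngle, p$pose@phi, p$pose@psi)
  })
  expect_true(all(abs(draws[1, ] * 10 - round(draws[1, ] * 10)) < 1e-9))
  expect_true(all(draws[1, ] >= 1 & draws[1, ] <= 3))
  expect_true(all(draws[2, ] %in% 5:30))
  expect_true(all(draws[3, ] %in% -20:20))
  expect_equal(range(draws[3, ]), c(-20, 20))
  expect_true(all(draws[4, ] %in% -180:180))
  set.seed(99); a <- sampleSimParams(ranges)
  set.seed(99); b <- sampleSimParams(ranges)
  expect_identical(poseVector(a$pose), poseVector(b$pose))
  expect_error(simParamRanges(Rrange = c(3, 1)), "empty")
})
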