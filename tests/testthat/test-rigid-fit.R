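test_that("pixel correlation behaves like a Pearson correlation", {
  set.seed(61)
  a <- HeightImage(matrix(runif(144), 12L))
  b <- HeightImage(matrix(runif(144), 12L))
  expect_equal(ccScore(a, a), 1)
  expect_equal(ccScore(a, b), ccScore(b, a))
  # affine invariance
  expect_equal(ccScore(a, HeightImage(2.5 * heights(a) + 1)), 1)
  expect_equal(ccScore(a, HeightImage(-0.5 * heights(a) + 3)), -1)
  # textbook recomputation
  x <- as.numeric(heights(a)); y <- as.numeric(heights(b))
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ccScore(a, b), byHand, tolerance = 1e-10)
  expect_equal(ccScore(a, b), cor(x, y), tolerance = 1e-10)
  expect_error(ccScore(a, HeightImage(matrix(1, 12L, 12L))), "constant")
})

test_that("the default search grid matches the printed ranges", {
  g <- fitGrid()
  expect_length(g$psi, 73L)
  expect_length(g$phi, 13L)
  expect_length(g$theta, 13L)
  expect_equal(g$R, 1)
  expect_equal(g$Theta, 10)
  expect_equal(g$shiftPx, 3L)
  expect_error(fitGrid(psi = numeric(0)), "length")
})

fitFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- smallHinge()
      sm <- clusterGMM(fitPCA(fx$ensemble), kRange = 2:6, seed = 3)
      cache <<- list(fx = fx, sm = sm,
                     centers = lapply(stateCenters(sm),
                                      function(i) fx$ensemble[[i]]))
    }
    cache
  }
})

test_that("grid-aligned self-renders are recovered exactly", {
  d <- fitFixture()
  grid <- fitGrid(psi = seq(-180, 150, by = 30), phi = seq(-20, 20, by = 10),
                  theta = seq(-20, 20, by = 10), shiftPx = 1L)
  set.seed(62)
  for (i in 1:4) {
    state <- sample.int(length(d$centers), 1L)
    pose <- Pose(psi = sample(grid$psi, 1L), phi = sample(grid$phi, 1L),
                 theta = sample(grid$theta, 1L))
    img <- renderImage(d$centers[[state]], pose, TipModel(1, 10), ImageGrid())
    res <- rigidFit(img, d$centers, grid)
    expect_equal(res@state, state)
    expect_equal(poseVector(res@pose), poseVector(pose), tolerance = 1e-12)
    expect_equal(res@shift, c(0L, 0L))
    expect_gt(res@cc, 1 - 1e-9)
    # argmax dominance: nothing on the grid beats the true pose
    expect_gte(res@cc, ccScore(img, img) - 1e-9)
  }
})

test_that("fitting is invariant to affine intensity transforms", {
  d <- fitFixture()
  grid <- fitGrid(psi = seq(-180, 120, by = 60), phi = 0, theta = 0,
                  shiftPx = 1L)
  img <- renderImage(d$centers[[2L]], Pose(psi = -60), TipModel(1, 10),
                     ImageGrid())
  r1 <- rigidFit(img, d$centers, grid)
  r2 <- rigidFit(HeightImage(3 * heights(img) + 0.7, imageGrid(img)),
                 d$centers, grid)
  expect_equal(r1@state, r2@state)
  expect_identical(poseVector(r1@pose), poseVector(r2@pose))
  expect_equal(r1@cc, r2@cc, tolerance = 1e-9)
})

test_that("the score table is sorted and consistent with the argmax", {
  d <- fitFixture()
  grid <- fitGrid(psi = seq(-180, 120, by = 60), phi = 0, theta = 0,
                  shiftPx = 1L)
  img <- renderImage(d$centers[[1L]], Pose(psi = 0), TipModel(1, 10),
                     ImageGrid())
  res <- rigidFit(img, d$centers, grid, topN = 5L)
  expect_equal(nrow(res@table), 5L)
  expect_true(!is.unsorted(rev(res@table$cc)))
  expect_equal(res@table$cc[1L], res@cc)
  expect_equal(res@table$state[1L], res@state)
})

test_that("restricting candidates to one structure fits the pose only", {
  d <- fitFixture()
  model <- buildModel(deskModelConfig(length(d$centers)), seed = 5L)
  grid <- fitGrid(psi = seq(-180, 120, by = 60), phi = 0, theta = 0,
                  shiftPx = 1L)
  img <- renderImage(d$centers[[3L]], Pose(psi = 60), TipModel(1, 10),
                     ImageGrid())
  res <- fitAfterDenoise(img, model, d$centers, grid, fitDenoised = FALSE)
  pred <- attr(res, "prediction")
  # the state is the network's assignment, not the correlation argmax
  expect_equal(res@state, pred$stateHat)
  direct <- rigidFit(img, d$centers[pred$stateHat], grid)
  expect_identical(poseVector(res@pose), poseVector(direct@pose))
  expect_equal(res@cc, direct@cc)
})
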