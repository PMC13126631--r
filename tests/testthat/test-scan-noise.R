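test_that("degenerate noise parameters give the zero perturbation", {
  expect_equal(unname(sampleLinePerturbation(ScanNoiseParams(s = 0))),
               rep(0, 5))
  expect_equal(unname(sampleLinePerturbation(ScanNoiseParams(w = 0))),
               rep(0, 5))
  expect_equal(max(abs(sampleLinePerturbations(100, ScanNoiseParams(s = 0)))), 0)
})

test_that("perturbations match a truncated-normal oracle", {
  p <- ScanNoiseParams()  # sigma_psi = 5 deg, bound 10 deg
  set.seed(21)
  draws <- sampleLinePerturbations(5e4, p)
  # independent oracle: plain rejection sampling with rnorm
  ora <- rnorm(2e5, 0, 5)
  ora <- ora[abs(ora) <= 10][1:5e4]
  vHat <- var(draws[, "dpsi"])
  vOra <- var(ora)
  se <- sqrt(2 / 5e4) * vOra
  expect_lt(abs(vHat - vOra), 6 * se)
  # all truncation bounds hold
  expect_true(all(sqrt(draws[, 1]^2 + draws[, 2]^2) <= p@w * p@drMax))
  expect_true(all(abs(draws[, "dphi"]) <= p@w * p@dphiMax))
  expect_true(all(abs(draws[, "dpsi"]) <= p@w * p@dpsiMax))
})

test_that("large variance scaling drives the distribution toward uniform", {
  set.seed(22)
  draws <- sampleLinePerturbations(5e4, ScanNoiseParams(s = 10))
  x <- sort(draws[, "dpsi"])
  unifCDF <- (x + 10) / 20
  empCDF <- seq_along(x) / length(x)
  expect_lt(max(abs(empCDF - unifCDF)), 0.03)
})

test_that("scan-lag rendering degenerates to the static render bit-exactly", {
  fx <- smallHinge()
  m <- fx$ensemble[[1L]]
  set.seed(5)
  a <- renderWithScanLag(m, Pose(psi = 25), TipModel(), ImageGrid(),
                         ScanNoiseParams(s = 0))
  b <- renderImage(m, Pose(psi = 25), TipModel(), ImageGrid())
  expect_identical(heights(a), heights(b))
  set.seed(5)
  w0 <- renderWithScanLag(m, Pose(psi = 25), TipModel(), ImageGrid(),
                          ScanNoiseParams(w = 0))
  expect_identical(heights(w0), heights(b))
})

test_that("scan-lag rendering is seeded and replays per line", {
  fx <- smallHinge()
  m <- fx$ensemble[[2L]]
  grid <- ImageGrid()
  set.seed(77)
  r1 <- renderWithScanLag(m, Pose(), TipModel(), grid, ScanNoiseParams(),
                          returnPerturbations = TRUE)
  set.seed(77)
  r2 <- renderWithScanLag(m, Pose(), TipModel(), grid, ScanNoiseParams())
  expect_identical(heights(r1$image), heights(r2))
  # replay: re-rendering line k with its logged perturbation reproduces it
  for (k in c(1L, 17L, 36L)) {
    d <- r1$perturbations[k, ]
    pose <- Pose(x = d[["dx"]], y = d[["dy"]], phi = d[["dphi"]],
                 theta = d[["dtheta"]], psi = d[["dpsi"]])
    line <- afmstate:::.renderPosedRows(m, pose, TipModel(), grid, k)
    expect_identical(as.numeric(heights(r1$image)[k, ]), as.numeric(line))
  }
})

test_that("white noise has the requested scale and preserves the mean", {
  img <- HeightImage(matrix(0, 36, 36))
  expect_identical(heights(addWhiteNoise(img, 0)), heights(img))
  set.seed(9)
  reps <- replicate(40, {
    n <- addWhiteNoise(img, 0.3)
    c(sd(heights(n)), mean(heights(n)))
  })
  # sample sd of 1296 pixels: SE ~ sigma/sqrt(2*1295)
  expect_lt(abs(mean(reps[1, ]) - 0.3), 3 * 0.3 / sqrt(2 * 1295 * 40))
  expect_lt(abs(mean(reps[2, ])), 3 * 0.3 / sqrt(1296 * 40))
  expect_error(addWhiteNoise(img, -0.1), ">= 0")
})

test_that("sigma_N draws lie on the printed grid", {
  set.seed(4)
  draws <- replicate(3000, sampleSigmaN())
  expect_true(all(abs(draws * 100 - round(draws * 100)) < 1e-9))
  expect_true(all(draws >= 0 & draws <= 0.3))
  expect_equal(sampleSigmaN(0, 0), 0)
  set.seed(8); a <- sampleSigmaN()
  set.seed(8); b <- sampleSigmaN()
  expect_identical(a, b)
})

test_that("pixel shifts move content and distribute uniformly", {
  v <- matrix(0, 10, 10); v[4, 6] <- 1
  img <- HeightImage(v)
  s0 <- shiftImage(img, 0, 0)
  expect_identical(heights(s0), v)
  s1 <- shiftImage(img, 1, 0)
  expect_equal(which(heights(s1) == 1, arr.ind = TRUE)[1, ],
               c(row = 4, col = 7))
  s2 <- shiftImage(img, 0, -2)
  expect_equal(which(heights(s2) == 1, arr.ind = TRUE)[1, ],
               c(row = 2, col = 6))
  expect_error(shiftImage(img, 11, 0), "larger than image")

  set.seed(13)
  g <- HeightImage(matrix(runif(100), 10))
  n <- HeightImage(matrix(runif(100), 10))
  counts <- table(replicate(6000, {
    r <- randomPixelShift(g, n, 3L)
    paste(r$shift, collapse = ",")
  }))
  expect_equal(length(counts), 49L)
  expect_gt(chisq.test(as.numeric(counts))$p.value, 1e-4)
})

test_that("both pair members receive the identical augmentation shift", {
  set.seed(31)
  g <- HeightImage(matrix(rnorm(400), 20))
  n <- HeightImage(matrix(rnorm(400), 20))
  r <- randomPixelShift(g, n, 3L)
  expect_identical(heights(r$gt),
                   heights(shiftImage(g, r$shift[1], r$shift[2])))
  expect_identical(heights(r$noisy),
                   heights(shiftImage(n, r$shift[1], r$shift[2])))
})
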