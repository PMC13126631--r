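# Small ensembles and coarse grids keep dataset tests fast.
dsFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- smallHinge()
      sm0 <- fitPCA(fx$ensemble)
      cache <<- list(fx = fx, sm = clusterGMM(sm0, kRange = 2:6, seed = 2))
    }
    cache
  }
})

smallGrid <- function() ImageGrid(12L, 12L, 2.4)

test_that("min-max normalization and rescaling invert each other", {
  img <- HeightImage(matrix(c(0, 2, 1, 0.5), 2L))
  nrm <- minmaxNormalize(img)
  expect_equal(nrm$vmin, 0)
  expect_equal(nrm$vmax, 2)
  expect_equal(nrm$values01, matrix(c(0, 1, 0.5, 0.25), 2L))
  flat <- minmaxNormalize(HeightImage(matrix(3, 4L, 4L)))
  expect_equal(flat$values01, matrix(0, 4L, 4L))
  expect_equal(flat$vmin, flat$vmax)
  set.seed(51)
  v <- matrix(runif(100, -2, 5), 10L)
  nr <- minmaxNormalize(v)
  back <- minmaxRescale(nr$values01, nr$vmin, nr$vmax)
  expect_lt(max(abs(heights(back) - v)), 1e-12)
})

test_that("shards hold the requested pair counts with zero-padded keys", {
  d <- dsFixture()
  dir <- tempfile("ds")
  paths <- buildDataset(d$fx$ensemble, d$sm, nPairs = 10L, dir = dir,
                       grid = smallGrid(), shardSize = 4L, seed = 9L)
  expect_length(paths, 3L)
  members <- lapply(paths, function(p) utils::untar(p, list = TRUE))
  expect_equal(lengths(members), c(12L, 12L, 6L))  # 3 files per pair
  keys <- sort(unique(sub("\\..*$", "", unlist(members))))
  expect_identical(keys, sprintf("%010d", 0:9))
})

test_that("dataset generation is deterministic per (seed, shard)", {
  d <- dsFixture()
  dirA <- tempfile(); dirB <- tempfile()
  a <- buildDataset(d$fx$ensemble, d$sm, 6L, dirA, grid = smallGrid(),
                    shardSize = 3L, seed = 4L)
  b <- buildDataset(d$fx$ensemble, d$sm, 6L, dirB, grid = smallGrid(),
                    shardSize = 3L, seed = 4L)
  for (s in 1:2)
    expect_identical(readBin(a[s], "raw", file.size(a[s])),
                     readBin(b[s], "raw", file.size(b[s])))
  c1 <- buildDataset(d$fx$ensemble, d$sm, 6L, tempfile(), grid = smallGrid(),
                     shardSize = 3L, seed = 5L)
  expect_false(identical(readBin(a[1], "raw", file.size(a[1])),
                         readBin(c1[1], "raw", file.size(c1[1]))))
})

test_that("stored ground truth re-renders from its own metadata", {
  d <- dsFixture()
  dir <- tempfile("ds")
  buildDataset(d$fx$ensemble, d$sm, 5L, dir, grid = smallGrid(), seed = 12L)
  ds <- readDataset(dir)
  expect_equal(nrow(ds$gt), 5L)
  ex <- tempfile(); utils::untar(list.files(dir, full.names = TRUE)[1L], exdir = ex)
  for (key in ds$keys[1:3]) {
    meta <- jsonlite::read_json(file.path(ex, paste0(key, ".json")),
                                simplifyVector = TRUE)
    frame <- which(frameIds(d$fx$ensemble) == meta$frame_id)
    img <- renderImage(d$fx$ensemble[[frame]],
                       Pose(x = meta$pose0$x, y = meta$pose0$y,
                            phi = meta$pose0$phi, theta = meta$pose0$theta,
                            psi = meta$pose0$psi),
                       TipModel(meta$R, meta$Theta), smallGrid())
    stored <- matrix(ds$gt[which(ds$keys == key), ], 12L, 12L)
    expect_lt(max(abs(stored - heights(img))), 4e-6)  # float32 storage
    expect_equal(meta$state, stateLabels(d$sm)[frame])
  }
})

test_that("frames are drawn uniformly so labels match state occupancy", {
  d <- dsFixture()
  dir <- tempfile("ds")
  buildDataset(d$fx$ensemble, d$sm, 400L, dir, grid = ImageGrid(6L, 6L, 4.8),
               shardSize = 400L, seed = 21L)
  ds <- readDataset(dir)
  occ <- tabulate(stateLabels(d$sm), nStates(d$sm)) / nConformers(d$fx$ensemble)
  cnt <- tabulate(ds$state, nStates(d$sm))
  p <- chisq.test(cnt, p = occ)$p.value
  expect_gt(p, 0.001)
})

test_that("streaming visits every key once and honors transforms", {
  d <- dsFixture()
  dir <- tempfile("ds")
  buildDataset(d$fx$ensemble, d$sm, 8L, dir, grid = smallGrid(),
               shardSize = 3L, seed = 6L, sigmaRange = c(0, 0))
  st <- streamBatches(dir, batchSize = 3L, augment = FALSE, addNoise = FALSE,
                      shuffle = TRUE, seed = 1L)
  seen <- character(0)
  repeat {
    b <- st$nextBatch()
    if (is.null(b)) break
    seen <- c(seen, b$keys)
  }
  expect_identical(sort(seen), sprintf("%010d", 0:7))
  expect_equal(anyDuplicated(seen), 0L)
  # with sigma_N = 0 and no augmentation the loaded pair equals the stored
  # pair after normalization
  ds <- readDataset(dir)
  st$reset()
  b <- st$nextBatch()
  i <- which(ds$keys == b$keys[1L])
  nrm <- minmaxNormalize(matrix(ds$noisy[i, ], 12L))
  expect_equal(matrix(b$noisy01[1L, ], 12L), nrm$values01, tolerance = 1e-7)
})

test_that("augmentation shifts both members jointly (recoverable by
           cross-correlation)", {
  d <- dsFixture()
  dir <- tempfile("ds")
  buildDataset(d$fx$ensemble, d$sm, 4L, dir, grid = smallGrid(),
               shardSize = 4L, seed = 8L, sigmaRange = c(0, 0))
  ds <- readDataset(dir)
  st <- streamBatches(dir, batchSize = 4L, augment = TRUE, addNoise = FALSE,
                      shuffle = FALSE, seed = 3L)
  b <- st$nextBatch()
  bestLag <- function(stored, loaded) {
    sc <- expand.grid(dx = -3:3, dy = -3:3)
    cors <- apply(sc, 1L, function(s) {
      sh <- afmstate:::.shiftMatrix(stored, s[1L], s[2L])
      if (sd(sh) == 0) return(-2)
      cor(as.numeric(sh), as.numeric(loaded))
    })
    unlist(sc[which.max(cors), ])
  }
  for (i in 1:4) {
    k <- which(ds$keys == b$keys[i])
    gtLag <- bestLag(matrix(ds$gt[k, ], 12L), matrix(b$gt01[i, ], 12L))
    noLag <- bestLag(matrix(ds$noisy[k, ], 12L), matrix(b$noisy01[i, ], 12L))
    expect_identical(gtLag, noLag)
  }
})

test_that("in-memory pair generation is deterministic and labelled", {
  d <- dsFixture()
  a <- makeTrainingPairs(d$fx$ensemble, d$fx$labels, 12L, grid = smallGrid(),
                         seed = 31L)
  b <- makeTrainingPairs(d$fx$ensemble, d$fx$labels, 12L, grid = smallGrid(),
                         seed = 31L)
  expect_identical(a$gt, b$gt)
  expect_identical(a$noisy, b$noisy)
  expect_identical(a$state, b$state)
  expect_identical(a$state, d$fx$labels[a$frame])
})
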