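test_that("superposition removes rigid-body motion", {
  set.seed(17)
  a <- BeadModel(matrix(rnorm(30), 10L), 0.5, "ALA")
  expect_equal(superpose(a, a)$rmsd, 0)
  b <- BeadModel(coords(a) + rep(c(3, -2, 1), each = 10L), 0.5, "ALA")
  expect_lt(superpose(a, b)$rmsd, 1e-10)
  R <- afmstate:::.rotZXY(35, -12, 60)
  c3 <- BeadModel(coords(a) %*% t(R), 0.5, "ALA")
  expect_lt(superpose(a, c3)$rmsd, 1e-10)
  # 90-degree rotated two-point pair (padded to 3 beads for rank)
  p1 <- BeadModel(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)), 0.3, "X")
  p2 <- BeadModel(rbind(c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0)), 0.3, "X")
  expect_lt(superpose(p1, p2)$rmsd, 1e-10)
})

test_that("superposed RMSD matches the bio3d oracle", {
  set.seed(18)
  for (i in 1:5) {
    a <- matrix(rnorm(36), 12L)
    b <- a + matrix(rnorm(36, 0, 0.4), 12L)
    ours <- superpose(BeadModel(a, 1, "X"), BeadModel(b, 1, "X"))$rmsd
    ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
    expect_lt(abs(ours - ref), 5e-4)  # bio3d prints to 3 decimals
  }
})

test_that("degenerate geometries are rejected", {
  line <- BeadModel(cbind(1:5, 0, 0), 1, "X")
  expect_error(superpose(line, line), "collinear")
  a <- BeadModel(matrix(rnorm(30), 10L), 1, "X")
  b <- BeadModel(matrix(rnorm(15), 5L), 1, "X")
  expect_error(superpose(a, b), "bead counts differ")
})

test_that("PCA captures a one-dimensional motion in PC1", {
  set.seed(16)
  base <- matrix(rnorm(24), 8L)
  dirv <- matrix(rnorm(24), 8L); dirv <- dirv / sqrt(sum(dirv^2))
  conf <- lapply(seq(-2, 2, length.out = 11), function(t)
    BeadModel(base + t * dirv, 0.5, "X"))
  # rank-1 variation: a warning reports the reduced component count
  expect_warning(fitPCA(Ensemble(conf), nPC = 3L, align = FALSE),
                 "rank-deficient")
  sm <- suppressWarnings(fitPCA(Ensemble(conf), nPC = 3L, align = FALSE))
  expect_equal(sm@nPC, 1L)
  varFrac <- sm@sdev[1L]^2 / sum(sm@sdev^2)
  expect_gt(varFrac, 1 - 1e-9)
})

test_that("PCA basis is orthonormal and centers the data", {
  set.seed(25)
  conf <- lapply(1:20, function(i) BeadModel(matrix(rnorm(24), 8L), 0.5, "X"))
  sm <- fitPCA(Ensemble(conf), nPC = 3L, align = FALSE)
  expect_equal(unname(crossprod(sm@pcaComponents)), diag(3L),
               tolerance = 1e-9)
  meanFlat <- colMeans(t(vapply(conf, function(m) as.numeric(t(coords(m))),
                                numeric(24))))
  expect_lt(max(abs((meanFlat - sm@pcaMean) %*% sm@pcaComponents)), 1e-9)
})

test_that("PCA reconstruction error equals the discarded eigenvalue mass", {
  set.seed(19)
  conf <- lapply(1:30, function(i) BeadModel(matrix(rnorm(18), 6L), 0.5, "X"))
  ens <- Ensemble(conf)
  sm <- fitPCA(ens, nPC = 4L, align = FALSE)
  X <- t(vapply(conf, function(m) as.numeric(t(coords(m))), numeric(18)))
  Xc <- sweep(X, 2L, sm@pcaMean)
  resid <- Xc - sm@projections %*% t(sm@pcaComponents)
  # full eigendecomposition oracle
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(sum(resid^2) / (nrow(X) - 1), sum(ev[-(1:4)]),
               tolerance = 1e-8)
})

test_that("BIC selects the correct count for well-separated mixtures", {
  set.seed(20)
  blob <- function(mu, n) sweep(matrix(rnorm(n * 3), n), 2L, mu, `+`)
  proj <- rbind(blob(c(-5, 0, 0), 250), blob(c(5, 0, 0), 250))
  sm0 <- new("StateModel", pcaMean = numeric(3), sdev = rep(1, 3),
             pcaComponents = diag(3), nPC = 3L, projections = proj,
             labels = integer(0), centers = integer(0), K = 0L,
             orderKey = numeric(0), bicTable = numeric(0))
  sm <- clusterGMM(sm0, kRange = 1:4, seed = 5)
  expect_equal(nStates(sm), 2L)
  # mclust's own model selection over the same range agrees
  ref <- mclust::Mclust(proj, G = 1:4, modelNames = "VVV", verbose = FALSE)
  expect_equal(ref$G, 2L)
  # labels 1 and 2 follow mean PC1 (blob at -5 is state 1)
  expect_lt(mean(proj[stateLabels(sm) == 1L, 1L]),
            mean(proj[stateLabels(sm) == 2L, 1L]))
  expect_true(!is.unsorted(sm@orderKey))
})

test_that("hinge states are recovered with PC1-ordered labels", {
  d <- defaultHinge()
  fx <- d$fx
  sm <- d$sm
  expect_equal(nStates(sm), 4L)
  expect_gt(mclust::adjustedRandIndex(stateLabels(sm), fx$labels), 0.95)
  # relabelling preserves the partition (same groups as sets)
  expect_true(!is.unsorted(sm@orderKey))
  # ordered labels follow the planted order up to global reversal
  tab <- table(stateLabels(sm), fx$labels)
  perm <- apply(tab, 1L, which.max)
  expect_true(all(perm == 1:4) || all(perm == 4:1))
  # nearest-to-mean center rule, checked by brute force
  for (k in seq_len(nStates(sm))) {
    members <- which(stateLabels(sm) == k)
    mu <- colMeans(projections(sm)[members, , drop = FALSE])
    d2 <- rowSums(sweep(projections(sm)[members, , drop = FALSE], 2L, mu)^2)
    expect_equal(stateCenters(sm)[k], members[which.min(d2)])
  }
})

test_that("state RMSD statistics match an exhaustive oracle", {
  d <- defaultHinge()
  ens <- d$fx$ensemble
  sm <- d$sm
  st <- stateRmsdStats(ens, sm, maxMembers = 25L)
  expect_length(st$within, 4L)
  expect_length(st$between, 3L)
  # oracle for state 1 with the same deterministic subsample
  members <- which(stateLabels(sm) == 1L)
  members <- members[unique(round(seq(1L, length(members), length.out = 25L)))]
  tot <- 0; np <- 0L
  for (i in seq_len(length(members) - 1L))
    for (j in (i + 1L):length(members)) {
      tot <- tot + superpose(ens[[members[i]]], ens[[members[j]]])$rmsd
      np <- np + 1L
    }
  expect_equal(st$within[1L], tot / np, tolerance = 1e-12)
  # i.i.d. jitter sigma = 0.15 nm/coordinate: mean pairwise superposed RMSD
  # is about sqrt(6) * sigma = 0.37 nm; adjacent planted states are well
  # beyond the thermal spread
  expect_true(all(abs(st$within - sqrt(6) * 0.15) < 0.1))
  expect_true(all(st$between > 1.5 * max(st$within)))
})

test_that("identical conformers give all-zero RMSD statistics", {
  bm <- twoBeadModel()
  bm3 <- BeadModel(rbind(coords(bm), c(0, 2, 1)), c(radii(bm), 0.5),
                   c(kinds(bm), "X"))
  ens <- Ensemble(rep(list(bm3), 12L))
  sm0 <- new("StateModel", pcaMean = numeric(9), sdev = rep(1, 2),
             pcaComponents = matrix(0, 9, 2), nPC = 2L,
             projections = matrix(0, 12, 2),
             labels = rep(c(1L, 2L), each = 6L), centers = c(1L, 7L),
             K = 2L, orderKey = c(0, 0), bicTable = numeric(0))
  st <- stateRmsdStats(ens, sm0)
  expect_equal(st$within, c(0, 0))
  expect_equal(st$between, 0)
})

test_that("state models persist and reload", {
  d <- defaultHinge()
  fx <- d$fx
  sm <- d$sm
  dir <- tempfile("sm")
  saveStateModel(sm, dir, fx$ensemble)
  expect_true(file.exists(file.path(dir, "centers.pdb")))
  sm2 <- loadStateModel(dir)
  expect_equal(nStates(sm2), nStates(sm))
  expect_identical(stateLabels(sm2), stateLabels(sm))
  expect_identical(stateCenters(sm2), stateCenters(sm))
  expect_equal(projections(sm2), unname(projections(sm)), tolerance = 1e-12)
  expect_equal(sm2@pcaComponents, unname(sm@pcaComponents),
               tolerance = 1e-12)
  # center text export round-trips the center conformers
  cens <- readBeadText(file.path(dir, "centers.txt"))
  expect_equal(unname(coords(cens[[1L]])),
               unname(coords(fx$ensemble[[stateCenters(sm)[1L]]])))
})
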