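test_that("token layout follows the patch grid", {
  cfg <- modelConfig(nStates = 4L)
  expect_equal(cfg$nPatch, 36L)  # 36/6 = 6 x 6 patches
  expect_error(modelConfig(4L, imagePx = 36L, patchPx = 5L), "divisible")
  expect_error(modelConfig(4L, encDim = 130L), "divisible by heads")
  idx <- afmstate:::.patchIndex(12L, 6L)
  expect_equal(dim(idx), c(4L, 36L))
  expect_identical(sort(as.integer(idx)), 1:144)
  # patchify/unpatchify are inverse
  X <- matrix(rnorm(3 * 144), 3L)
  tok <- afmstate:::.patchify(X, idx)
  expect_equal(afmstate:::.unpatchify(tok, idx, 3L), X)
})

test_that("encoder outweighs the decoder under the reference dimensions", {
  model <- buildModel(modelConfig(nStates = 19L), seed = 1L)
  np <- countParams(model)
  expect_gt(np["encoder"], np["decoder"])
  # analytic block count: a transformer block at width D with MLP ratio 4
  # holds 12 D^2 + 13 D parameters
  blockParams <- function(D) 12 * D^2 + 13 * D
  expect_equal(unname(np["encoder"]),
               37 * 512 + 512 + 37 * 512 + 12 * blockParams(512))
})

test_that("analytic gradients match finite differences (reference path)", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 3L)
  set.seed(9)
  B <- 2L
  X <- matrix(runif(B * 144), B)
  gt <- matrix(runif(B * 144), B)
  y <- c(1L, 3L)
  lossOf <- function(P) {
    m <- model; m$params <- P
    fwd <- afmstate:::.forwardAE(m, X)
    probs <- afmstate:::.softmaxRows(fwd$logits)
    100 * mean((gt - fwd$out01)^2) - mean(log(probs[cbind(1:B, y)]))
  }
  fwd <- afmstate:::.forwardAE(model, X)
  probs <- afmstate:::.softmaxRows(fwd$logits)
  dOut <- 100 * 2 * (fwd$out01 - gt) / (B * 144)
  onehot <- matrix(0, B, 3L); onehot[cbind(1:B, y)] <- 1
  grads <- afmstate:::.backwardAE(model, fwd, dOut, (probs - onehot) / B)
  set.seed(10)
  eps <- 1e-5
  for (nm in sample(names(model$params))) {
    i <- sample.int(length(model$params[[nm]]), 1L)
    P2 <- model$params; P2[[nm]][i] <- P2[[nm]][i] + eps
    P3 <- model$params; P3[[nm]][i] <- P3[[nm]][i] - eps
    num <- (lossOf(P2) - lossOf(P3)) / (2 * eps)
    ana <- grads[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 5e-3)
  }
})

test_that("the compiled engine reproduces the reference implementation", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 3L)
  set.seed(9)
  B <- 3L
  X <- matrix(runif(B * 144), B)
  gt <- matrix(runif(B * 144), B)
  y <- c(1L, 3L, 2L)
  fwd <- afmstate:::.forwardAE(model, X)
  probs <- afmstate:::.softmaxRows(fwd$logits)
  dOut <- 100 * 2 * (fwd$out01 - gt) / (B * 144)
  onehot <- matrix(0, B, 3L); onehot[cbind(1:B, y)] <- 1
  ref <- afmstate:::.backwardAE(model, fwd, dOut, (probs - onehot) / B)
  stp <- afmstate:::.cpp_ae_step(model$params, model$cfg, X, gt, y, 100, 1)
  expect_lt(max(abs(stp$grads[["embed.W"]] - ref[["embed.W"]])), 1e-5)
  worst <- max(vapply(names(ref), function(nm) {
    a <- as.numeric(ref[[nm]]); b <- as.numeric(stp$grads[[nm]])
    max(abs(a - b)) / max(1e-6, max(abs(a)))
  }, numeric(1)))
  expect_lt(worst, 1e-3)
  pr <- afmstate:::.cpp_ae_predict(model$params, model$cfg, X, FALSE)
  expect_lt(max(abs(pr$out01 - fwd$out01)), 1e-5)
  expect_lt(max(abs(pr$logits - fwd$logits)), 1e-5)
})

test_that("loss obeys the closed-form weighted composition", {
  pred <- list(denoised01 = matrix(0.5, 1L, 4L), probs = c(1, 0, 0))
  expect_equal(as.numeric(aeLoss(pred, matrix(0.5, 1L, 4L), 1L)), 0)
  # alpha = 100, beta = 0: uniform error 0.1 gives exactly 1.0
  pred2 <- list(denoised01 = matrix(0.4, 1L, 4L), probs = c(1, 0, 0))
  expect_equal(as.numeric(aeLoss(pred2, matrix(0.5, 1L, 4L), 1L,
                                 alpha = 100, beta = 0)), 1.0)
  set.seed(12)
  den <- matrix(runif(8), 2L); gtv <- matrix(runif(8), 2L)
  pm <- matrix(rexp(6), 2L); pm <- pm / rowSums(pm)
  y <- c(2L, 3L)
  L <- aeLoss(list(denoised01 = den, probs = pm), gtv, y, 100, 1)
  byHand <- 100 * mean((gtv - den)^2) +
    mean(-log(c(pm[1, 2], pm[2, 3])))
  expect_equal(as.numeric(L), byHand, tolerance = 1e-6)
  expect_equal(attr(L, "Ld"), mean((gtv - den)^2))
})

test_that("learning-rate schedule hits its endpoints", {
  expect_equal(lrSchedule(0, 100, 20, 0.002), 0)
  expect_equal(lrSchedule(20, 100, 20, 0.002), 0.002)
  expect_lt(lrSchedule(100, 100, 20, 0.002), 1e-10)
  mid <- lrSchedule(60, 100, 20, 0.002)
  expect_equal(mid, 0.002 * 0.5 * (1 + cos(pi * 0.5)))
})

test_that("a short smoke run trains and records history", {
  cfg <- tinyModelConfig()
  set.seed(1)
  n <- 64L
  data <- list(gt = matrix(runif(n * 144), n), noisy = matrix(runif(n * 144), n),
               state = sample.int(3L, n, TRUE), sigmaN = rep(0, n))
  model <- buildModel(cfg, seed = 2L)
  model <- trainAE(model, data, trainConfig(epochs = 2L, batch = 32L,
                                            warmupEpochs = 1L, seed = 5L))
  expect_equal(nrow(model$history), 2L)
  expect_true(all(is.finite(model$history$Ld)))
  expect_true(all(is.finite(model$history$Lc)))
})

test_that("inference returns a simplex, matching shapes and nm rescaling", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 4L)
  img <- HeightImage(matrix(runif(144, 0, 3), 12L))
  pred <- inferAE(model, img)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-6)
  expect_true(all(pred$probs >= 0))
  expect_equal(dim(pred$denoised01), c(12L, 12L))
  expect_equal(dim(heights(pred$denoisedNm)), c(12L, 12L))
  nrm <- minmaxNormalize(img)
  expect_equal(heights(pred$denoisedNm),
               pred$denoised01 * (nrm$vmax - nrm$vmin) + nrm$vmin,
               tolerance = 1e-9)
  expect_error(inferAE(model, HeightImage(matrix(0, 5, 5))), "12 x 12")
})

test_that("checkpoints round-trip bit-stably through save and load", {
  cfg <- tinyModelConfig()
  model <- buildModel(cfg, seed = 6L)
  img <- HeightImage(matrix(runif(144), 12L))
  p1 <- inferAE(model, img)
  dir <- tempfile("ckpt")
  saveCheckpoint(model, dir)
  model2 <- loadCheckpoint(dir)
  expect_identical(model2$params, model$params)
  p2 <- inferAE(model2, img)
  expect_identical(p1$probs, p2$probs)
  expect_identical(p1$denoised01, p2$denoised01)
})

test_that("attention rollout follows the residual-blended product", {
  cfg <- tinyModelConfig()  # nPatch = 4, T = 5
  # all-identity attention: uniform map
  ident <- lapply(1:2, function(i) diag(5L))
  m <- afmstate:::.rolloutFromAtt(cfg, ident)
  expect_equal(sd(m), 0)
  # hand-computed single layer
  set.seed(13)
  A <- matrix(rexp(25), 5L); A <- A / rowSums(A)
  got <- afmstate:::.rolloutFromAtt(cfg, list(A))
  Ab <- 0.5 * (A + diag(5L)); Ab <- Ab / rowSums(Ab)
  v <- (Ab %*% diag(5L))[1L, -1L]
  want <- kronecker(matrix(v, 2L, 2L, byrow = TRUE), matrix(1, 6L, 6L))
  want <- (want - min(want)) / (max(want) - min(want))
  expect_equal(got, want, tolerance = 1e-12)
  # on a real network the map is normalized to [0, 1]
  model <- buildModel(cfg, seed = 8L)
  roll <- attentionRollout(model, HeightImage(matrix(runif(144), 12L)))
  expect_equal(min(roll), 0)
  expect_equal(max(roll), 1)
  expect_equal(dim(roll), c(12L, 12L))
})

test_that("transfer initialization copies what matches and freezes on
           request", {
  cfg <- tinyModelConfig(3L)
  src <- buildModel(cfg, seed = 2L)
  same <- transferInit(src, seed = 99L)
  expect_identical(same$params, src$params)
  X <- matrix(runif(144), 1L)
  expect_identical(afmstate:::.cpp_ae_predict(same$params, same$cfg, X, FALSE),
                   afmstate:::.cpp_ae_predict(src$params, src$cfg, X, FALSE))
  # new K: only the classifier output layer stays fresh
  cfg5 <- tinyModelConfig(5L)
  moved <- transferInit(src, cfg5, seed = 99L)
  expect_false(any(c("clsHead.W", "clsHead.b") %in% moved$copied))
  expect_true("enc1.Wqkv" %in% moved$copied)
  expect_equal(dim(moved$params[["clsHead.W"]]), c(8L, 5L))
  expect_identical(moved$params[["enc1.Wqkv"]], src$params[["enc1.Wqkv"]])
  # freezing keeps encoder weights fixed through a training step
  froz <- transferInit(src, freezeEncoder = TRUE, seed = 1L)
  n <- 32L
  data <- list(gt = matrix(runif(n * 144), n), noisy = matrix(runif(n * 144), n),
               state = sample.int(3L, n, TRUE), sigmaN = rep(0, n))
  trained <- trainAE(froz, data, trainConfig(epochs = 1L, batch = 16L,
                                             warmupEpochs = 0L, seed = 3L))
  expect_identical(trained$params[["enc1.Wqkv"]], src$params[["enc1.Wqkv"]])
  expect_false(identical(trained$params[["clsHead.W"]],
                         froz$params[["clsHead.W"]]))
})

test_that("with beta = 0 classification stays at chance while denoising
           improves", {
  cfg <- tinyModelConfig(3L)
  set.seed(44)
  n <- 180L
  gt <- matrix(runif(n * 144), n)
  noisy <- gt + matrix(rnorm(n * 144, 0, 0.2), n)
  state <- sample.int(3L, n, TRUE)
  data <- list(gt = gt[1:150, ], noisy = noisy[1:150, ],
               state = state[1:150], sigmaN = rep(0, 150))
  val <- list(gt = gt[151:180, ], noisy = noisy[151:180, ],
              state = state[151:180], sigmaN = rep(0, 30))
  model <- buildModel(cfg, seed = 5L)
  ev0 <- evalAE(model, val)
  model <- trainAE(model, data,
                   trainConfig(epochs = 6L, batch = 30L, warmupEpochs = 1L,
                               lrMax = 1e-3, alpha = 100, beta = 0,
                               seed = 9L))
  ev <- evalAE(model, val)
  expect_lt(ev$Ld, ev0$Ld)                 # denoising improved
  expect_lt(abs(ev$accuracy - 1 / 3), 0.25)  # classification near chance
})

test_that("the reference-scale architecture runs one step", {
  cfg <- modelConfig(nStates = 19L)
  model <- buildModel(cfg, seed = 1L)
  X <- matrix(runif(1296), 1L)
  gt <- matrix(runif(1296), 1L)
  stp <- afmstate:::.cpp_ae_step(model$params, model$cfg, X, gt, 7L, 100, 1)
  expect_true(is.finite(stp$loss))
  expect_equal(length(stp$grads), length(model$params))
  expect_true(all(is.finite(stp$grads[["embed.W"]])))
})
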