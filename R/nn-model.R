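## Multitask vision-transformer autoencoder.
##
## One encoder feeds two branches: a classifier (transformer blocks plus a
## linear head on the class token) that assigns the conformational state,
## and a lighter decoder (narrower and shallower than the encoder, in the
## spirit of asymmetric masked autoencoders) that reconstructs the
## noise-free image. The training loss is L = alpha * L_d + beta * L_c with
## L_d the mean squared error between the normalized ground-truth and
## denoised images and L_c the cross-entropy of the state prediction;
## alpha = 100, beta = 1 balances the two scales.

#' Model architecture configuration
#'
#' The reference architecture is a 12-layer/512-dim encoder with an
#' 8-layer/256-dim decoder. The desk-scale configuration used throughout
#' the tests (4/128 encoder, 2/64 decoder) is available via
#' \code{deskModelConfig}. Patch size 6 px on a 36 px image gives a 6 x 6
#' grid of 36 patch tokens plus one class token.
#'
#' @param nStates number of conformational states K.
#' @param imagePx image edge in pixels.
#' @param patchPx patch edge in pixels (must divide \code{imagePx}).
#' @param encLayers,encDim encoder depth and width.
#' @param decLayers,decDim decoder depth and width.
#' @param clsLayers classifier transformer depth.
#' @param heads attention heads (must divide both dims).
#' @param mlpRatio MLP hidden-width multiple.
#' @return a ModelConfig list.
#' @export
modelConfig <- function(nStates, imagePx = 36L, patchPx = 6L,
                        encLayers = 12L, encDim = 512L,
                        decLayers = 8L, decDim = 256L,
                        clsLayers = 2L, heads = 8L, mlpRatio = 4L) {
  if (imagePx %% patchPx != 0L) stop("imagePx must be divisible by patchPx")
  if (encDim %% heads != 0L || decDim %% heads != 0L)
    stop("dims must be divisible by heads")
  list(nStates = as.integer(nStates), imagePx = as.integer(imagePx),
       patchPx = as.integer(patchPx), encLayers = as.integer(encLayers),
       encDim = as.integer(encDim), decLayers = as.integer(decLayers),
       decDim = as.integer(decDim), clsLayers = as.integer(clsLayers),
       heads = as.integer(heads), mlpRatio = as.integer(mlpRatio),
       nPatch = as.integer((imagePx %/% patchPx)^2))
}

#' @rdname modelConfig
#' @export
deskModelConfig <- function(nStates) {
  modelConfig(nStates, encLayers = 4L, encDim = 128L, decLayers = 2L,
              decDim = 64L, clsLayers = 2L, heads = 4L)
}

#' Desk-scale training protocol
#'
#' The tested one-CPU recipe for the desk-scale model: 10 epochs, batch 12
#' (small batches buy the optimizer more steps at fixed data size), peak
#' learning rate 1e-3 with one warmup epoch then cosine decay. Used by the
#' acceptance script and the test suite; pair it with
#' \code{trainAE(augment = FALSE, addNoise = FALSE)} (see the methods
#' vignette for why the load-time randomization is off at this scale).
#'
#' @param seed training seed.
#' @return a \code{\link{trainConfig}}.
#' @export
deskTrainConfig <- function(seed = 7L) {
  trainConfig(epochs = 10L, batch = 12L, warmupEpochs = 1L, lrMax = 1e-3,
              alpha = 100, beta = 1, seed = seed)
}

#' Build an untrained autoencoder
#'
#' Parameters are initialized from N(0, 0.02^2) (biases and layer-norm
#' offsets at zero), fully determined by \code{seed}.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param seed initialization seed.
#' @return a model object (list of \code{params}, \code{cfg}, \code{freeze}).
#' @export
buildModel <- function(cfg, seed = 1L) {
  set.seed(deriveSeed(seed, "init"))
  rnorm01 <- function(n) rnorm(n)
  D <- cfg$encDim; Dd <- cfg$decDim
  p2 <- cfg$patchPx^2
  P <- list()
  P[["embed.W"]] <- .glorot(p2, D)
  P[["embed.b"]] <- rep(0, D)
  P[["embed.cls"]] <- rnorm01(D) * 0.02
  P[["embed.pos"]] <- matrix(rnorm01((cfg$nPatch + 1L) * D) * 0.02,
                             cfg$nPatch + 1L)
  for (l in seq_len(cfg$encLayers))
    P <- .initBlock(P, paste0("enc", l), D, cfg$mlpRatio, rnorm01)
  for (l in seq_len(cfg$clsLayers))
    P <- .initBlock(P, paste0("cls", l), D, cfg$mlpRatio, rnorm01)
  P[["clsHead.ln.g"]] <- rep(1, D)
  P[["clsHead.ln.b"]] <- rep(0, D)
  P[["clsHead.W"]] <- .glorot(D, cfg$nStates)
  P[["clsHead.b"]] <- rep(0, cfg$nStates)
  P[["dec.proj.W"]] <- .glorot(D, Dd)
  P[["dec.proj.b"]] <- rep(0, Dd)
  P[["dec.pos"]] <- matrix(rnorm01(cfg$nPatch * Dd) * 0.02, cfg$nPatch)
  for (l in seq_len(cfg$decLayers))
    P <- .initBlock(P, paste0("dec", l), Dd, cfg$mlpRatio, rnorm01)
  P[["dec.ln.g"]] <- rep(1, Dd)
  P[["dec.ln.b"]] <- rep(0, Dd)
  P[["dec.out.W"]] <- .glorot(Dd, p2)
  P[["dec.out.b"]] <- rep(0, p2)
  list(params = P, cfg = cfg, freeze = character(0))
}

#' Parameter counts by component
#'
#' @param model a model from \code{\link{buildModel}}.
#' @return named numeric: parameters in the encoder (embedding included),
#'   classifier and decoder.
#' @export
countParams <- function(model) {
  nm <- names(model$params)
  sizes <- vapply(model$params, length, numeric(1))
  grp <- ifelse(grepl("^(embed|enc)", nm), "encoder",
                ifelse(grepl("^(cls|clsHead)", nm), "classifier", "decoder"))
  tapply(sizes, grp, sum)[c("encoder", "classifier", "decoder")]
}

.forwardAE <- function(model, Ximg) {
  P <- model$params; cfg <- model$cfg
  B <- nrow(Ximg)
  Tn <- cfg$nPatch + 1L
  idxMat <- .patchIndex(cfg$imagePx, cfg$patchPx)
  tok <- .patchify(Ximg, idxMat)                     # (B*nPatch) x p2
  emb <- .linearF(tok, P[["embed.W"]], P[["embed.b"]])
  clsRows <- seq.int(1L, B * Tn, by = Tn)
  X <- matrix(0, B * Tn, cfg$encDim)
  X[clsRows, ] <- matrix(P[["embed.cls"]], B, cfg$encDim, byrow = TRUE)
  X[-clsRows, ] <- emb$out
  X <- X + P[["embed.pos"]][rep(seq_len(Tn), B), ]
  encCache <- vector("list", cfg$encLayers)
  for (l in seq_len(cfg$encLayers)) {
    bl <- .blockF(P, paste0("enc", l), X, B, Tn, cfg$heads)
    X <- bl$out
    encCache[[l]] <- bl$cache
  }
  ## classifier branch
  Xc <- X
  clsCache <- vector("list", cfg$clsLayers)
  for (l in seq_len(cfg$clsLayers)) {
    bl <- .blockF(P, paste0("cls", l), Xc, B, Tn, cfg$heads)
    Xc <- bl$out
    clsCache[[l]] <- bl$cache
  }
  clsTok <- Xc[clsRows, , drop = FALSE]
  lnH <- .layernormF(clsTok, P[["clsHead.ln.g"]], P[["clsHead.ln.b"]])
  head <- .linearF(lnH$out, P[["clsHead.W"]], P[["clsHead.b"]])
  logits <- head$out
  ## decoder branch
  patchTok <- X[-clsRows, , drop = FALSE]
  dproj <- .linearF(patchTok, P[["dec.proj.W"]], P[["dec.proj.b"]])
  Xd <- dproj$out + P[["dec.pos"]][rep(seq_len(cfg$nPatch), B), ]
  decCache <- vector("list", cfg$decLayers)
  for (l in seq_len(cfg$decLayers)) {
    bl <- .blockF(P, paste0("dec", l), Xd, B, cfg$nPatch, cfg$heads)
    Xd <- bl$out
    decCache[[l]] <- bl$cache
  }
  lnD <- .layernormF(Xd, P[["dec.ln.g"]], P[["dec.ln.b"]])
  pix <- .linearF(lnD$out, P[["dec.out.W"]], P[["dec.out.b"]])
  out01 <- .unpatchify(pix$out, idxMat, B)
  list(out01 = out01, logits = logits,
       cache = list(emb = emb, encCache = encCache, clsCache = clsCache,
                    lnH = lnH, head = head, dproj = dproj,
                    decCache = decCache, lnD = lnD, pix = pix,
                    clsRows = clsRows, idxMat = idxMat, B = B, Tn = Tn))
}

.backwardAE <- function(model, fwd, dOut01, dLogits) {
  P <- model$params; cfg <- model$cfg
  cc <- fwd$cache
  B <- cc$B; Tn <- cc$Tn; clsRows <- cc$clsRows
  grads <- list()
  ## decoder branch
  dPix <- .patchifyGrad(dOut01, cc$idxMat)
  l <- .linearB(cc$pix, P[["dec.out.W"]], dPix)
  grads[["dec.out.W"]] <- l$dW; grads[["dec.out.b"]] <- l$db
  ln <- .layernormB(cc$lnD, P[["dec.ln.g"]], l$dX)
  grads[["dec.ln.g"]] <- ln$dg; grads[["dec.ln.b"]] <- ln$db
  dXd <- ln$dX
  for (l in rev(seq_len(cfg$decLayers))) {
    bb <- .blockB(P, paste0("dec", l), cc$decCache[[l]], dXd, grads)
    dXd <- bb$dX; grads <- bb$grads
  }
  grads[["dec.pos"]] <- rowsum(dXd, rep(seq_len(cfg$nPatch), B))
  l <- .linearB(cc$dproj, P[["dec.proj.W"]], dXd)
  grads[["dec.proj.W"]] <- l$dW; grads[["dec.proj.b"]] <- l$db
  dXencDec <- matrix(0, B * Tn, cfg$encDim)
  dXencDec[-clsRows, ] <- l$dX
  ## classifier branch
  l <- .linearB(cc$head, P[["clsHead.W"]], dLogits)
  grads[["clsHead.W"]] <- l$dW; grads[["clsHead.b"]] <- l$db
  ln <- .layernormB(cc$lnH, P[["clsHead.ln.g"]], l$dX)
  grads[["clsHead.ln.g"]] <- ln$dg; grads[["clsHead.ln.b"]] <- ln$db
  dXc <- matrix(0, B * Tn, cfg$encDim)
  dXc[clsRows, ] <- ln$dX
  for (l in rev(seq_len(cfg$clsLayers))) {
    bb <- .blockB(P, paste0("cls", l), cc$clsCache[[l]], dXc, grads)
    dXc <- bb$dX; grads <- bb$grads
  }
  dX <- dXencDec + dXc
  for (l in rev(seq_len(cfg$encLayers))) {
    bb <- .blockB(P, paste0("enc", l), cc$encCache[[l]], dX, grads)
    dX <- bb$dX; grads <- bb$grads
  }
  grads[["embed.pos"]] <- rowsum(dX, rep(seq_len(Tn), B))
  grads[["embed.cls"]] <- colSums(dX[clsRows, , drop = FALSE])
  dTok <- dX[-clsRows, , drop = FALSE]
  l <- .linearB(cc$emb, P[["embed.W"]], dTok)
  grads[["embed.W"]] <- l$dW; grads[["embed.b"]] <- l$db
  grads
}

.softmaxRows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Multitask training loss
#'
#' L = alpha * mean((gt01 - denoised01)^2) + beta * crossEntropy(y), with
#' the cross-entropy averaged over the batch in nats.
#'
#' @param pred list with \code{denoised01} (matrix, one row per sample) and
#'   \code{probs} (matrix, one row per sample).
#' @param gt01 normalized ground-truth images, one row per sample.
#' @param y integer state labels.
#' @param alpha,beta loss weights (defaults 100 and 1).
#' @return the scalar loss, with components as attributes \code{Ld}, \code{Lc}.
#' @export
aeLoss <- function(pred, gt01, y, alpha = 100, beta = 1) {
  den <- rbind(pred$denoised01)
  probs <- rbind(pred$probs)
  gt01 <- rbind(gt01)
  Ld <- mean((gt01 - den)^2)
  pick <- probs[cbind(seq_along(y), y)]
  Lc <- mean(-log(pmax(pick, 1e-12)))
  L <- alpha * Ld + beta * Lc
  attr(L, "Ld") <- Ld
  attr(L, "Lc") <- Lc
  L
}

#' Optimization configuration
#'
#' Defaults follow the reference recipe: 20 epochs, batch 192, AdamW with
#' weight decay 1e-4, peak learning rate 0.002 reached by linear warmup over
#' the first 5 epochs then cosine-decayed to zero.
#'
#' @param epochs,batch,lrMax,warmupEpochs,weightDecay,alpha,beta,seed
#'   see slots of the same names in the description.
#' @param adamBeta2 second-moment decay of AdamW; smaller values adapt the
#'   step size faster, useful for short small-batch runs.
#' @return a TrainConfig list.
#' @export
trainConfig <- function(epochs = 20L, batch = 192L, lrMax = 0.002,
                        warmupEpochs = 5L, weightDecay = 1e-4,
                        alpha = 100, beta = 1, seed = 7L,
                        adamBeta2 = 0.999) {
  stopifnot(epochs >= 1L, batch >= 1L, lrMax > 0, alpha >= 0, beta >= 0,
            adamBeta2 > 0, adamBeta2 < 1)
  list(epochs = as.integer(epochs), batch = as.integer(batch),
       lrMax = lrMax, warmupEpochs = as.integer(warmupEpochs),
       weightDecay = weightDecay, alpha = alpha, beta = beta,
       seed = as.integer(seed), adamBeta2 = adamBeta2)
}

#' Learning-rate schedule
#'
#' Linear warmup from 0 to \code{lrMax} over \code{warmupSteps}, then cosine
#' decay to 0 at \code{totalSteps}.
#'
#' @param step current step (0-based).
#' @param totalSteps,warmupSteps schedule extents in steps.
#' @param lrMax peak learning rate.
#' @return the learning rate at \code{step}.
#' @export
lrSchedule <- function(step, totalSteps, warmupSteps, lrMax) {
  if (warmupSteps > 0 && step < warmupSteps) return(lrMax * step / warmupSteps)
  if (totalSteps <= warmupSteps) return(lrMax)
  frac <- (step - warmupSteps) / (totalSteps - warmupSteps)
  lrMax * 0.5 * (1 + cos(pi * min(frac, 1)))
}

.adamInit <- function(P) {
  list(m = lapply(P, function(p) p * 0), v = lapply(P, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(P, grads, st, lr, weightDecay, freeze,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  noDecay <- c("embed.pos", "embed.cls", "dec.pos")
  for (nm in names(P)) {
    if (nm %in% freeze) next
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    wd <- if (is.matrix(P[[nm]]) && !(nm %in% noDecay)) weightDecay else 0
    P[[nm]] <- P[[nm]] - lr * (upd + wd * P[[nm]])
  }
  list(P = P, st = st)
}

## Assemble a normalized training batch from raw nm images.
.makeBatch <- function(data, idx, augment, addNoise) {
  np <- ncol(data$gt)
  side <- as.integer(sqrt(np))
  noisy01 <- matrix(0, length(idx), np)
  gt01 <- matrix(0, length(idx), np)
  vmin <- numeric(length(idx)); vmax <- numeric(length(idx))
  for (i in seq_along(idx)) {
    s <- idx[i]
    tr <- .loadTransform(matrix(data$gt[s, ], side, side),
                         matrix(data$noisy[s, ], side, side),
                         data$sigmaN[s], augment, addNoise = addNoise)
    noisy01[i, ] <- as.numeric(tr$noisy01)
    gt01[i, ] <- as.numeric(tr$gt01)
    vmin[i] <- tr$vmin; vmax[i] <- tr$vmax
  }
  list(noisy01 = noisy01, gt01 = gt01, state = data$state[idx],
       vmin = vmin, vmax = vmax)
}

#' Train the multitask autoencoder
#'
#' AdamW with the warmup/cosine schedule. Per epoch the sample order is
#' reshuffled and each batch passes through the load-time pipeline
#' (optional joint pixel shift, white noise at the recorded sigma_N on the
#' noisy member, min-max normalization by the noisy member). Training
#' aborts, returning the last finite-loss state, if the loss diverges.
#'
#' @param model from \code{\link{buildModel}} or \code{\link{transferInit}}.
#' @param data training set: list with matrices \code{gt}, \code{noisy}
#'   (one row per sample, nm), \code{state}, \code{sigmaN} (as from
#'   \code{\link{readDataset}}).
#' @param tcfg a \code{\link{trainConfig}}.
#' @param val optional validation set (same shape); evaluated noise-free and
#'   unaugmented each epoch.
#' @param augment,addNoise load-time pipeline switches for training batches.
#' @param verbose print per-epoch progress.
#' @param engine \code{"compiled"} (the float32 compiled engine, default) or
#'   \code{"reference"} (the pure-R double-precision reference path; the two
#'   are cross-checked in the test suite).
#' @return the model with trained \code{params} plus a \code{history}
#'   data.frame (per-epoch losses and validation accuracy).
#' @export
trainAE <- function(model, data, tcfg = trainConfig(), val = NULL,
                    augment = TRUE, addNoise = TRUE, verbose = FALSE,
                    engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  if (max(data$state) > model$cfg$nStates || min(data$state) < 1L)
    stop("state labels must lie in 1..nStates of the model configuration")
  set.seed(deriveSeed(tcfg$seed, "train"))
  n <- nrow(data$gt)
  stepsPerEpoch <- max(1L, n %/% tcfg$batch)
  totalSteps <- tcfg$epochs * stepsPerEpoch
  warmupSteps <- tcfg$warmupEpochs * stepsPerEpoch
  st <- .adamInit(model$params)
  hist <- data.frame()
  step <- 0L
  lastGood <- model$params
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    epLd <- 0; epLc <- 0; epAccN <- 0; epN <- 0L
    for (bi in seq_len(stepsPerEpoch)) {
      idx <- ord[((bi - 1L) * tcfg$batch + 1L):(bi * tcfg$batch)]
      bt <- .makeBatch(data, idx, augment, addNoise)
      B <- length(idx)
      if (engine == "compiled") {
        stp <- .cpp_ae_step(model$params, model$cfg, bt$noisy01, bt$gt01,
                            as.integer(bt$state), tcfg$alpha, tcfg$beta)
        Ld <- stp$Ld; Lc <- stp$Lc; L <- stp$loss
        grads <- stp$grads
        epAccN <- epAccN + sum(max.col(stp$probs) == bt$state)
        epN <- epN + B
      } else {
        fwd <- .forwardAE(model, bt$noisy01)
        probs <- .softmaxRows(fwd$logits)
        Ld <- mean((bt$gt01 - fwd$out01)^2)
        pick <- probs[cbind(seq_len(B), bt$state)]
        Lc <- mean(-log(pmax(pick, 1e-12)))
        L <- tcfg$alpha * Ld + tcfg$beta * Lc
        if (is.finite(L)) {
          dOut <- tcfg$alpha * 2 * (fwd$out01 - bt$gt01) / (B * ncol(bt$gt01))
          onehot <- matrix(0, B, model$cfg$nStates)
          onehot[cbind(seq_len(B), bt$state)] <- 1
          dLogits <- tcfg$beta * (probs - onehot) / B
          grads <- .backwardAE(model, fwd, dOut, dLogits)
        }
      }
      if (!is.finite(L)) {
        warning("loss diverged at epoch ", ep, "; returning last good state")
        model$params <- lastGood
        model$history <- hist
        return(model)
      }
      lr <- lrSchedule(step, totalSteps, warmupSteps, tcfg$lrMax)
      upd <- .adamStep(model$params, grads, st, lr, tcfg$weightDecay,
                       model$freeze, beta2 = tcfg$adamBeta2 %||% 0.999)
      model$params <- upd$P; st <- upd$st
      step <- step + 1L
      epLd <- epLd + Ld; epLc <- epLc + Lc
    }
    lastGood <- model$params
    row <- data.frame(epoch = ep, Ld = epLd / stepsPerEpoch,
                      Lc = epLc / stepsPerEpoch,
                      trainAcc = if (epN > 0) epAccN / epN else NA_real_,
                      valLd = NA_real_, valLc = NA_real_, valAcc = NA_real_)
    if (!is.null(val)) {
      ev <- evalAE(model, val, addNoise = FALSE, augment = FALSE)
      row$valLd <- ev$Ld; row$valLc <- ev$Lc; row$valAcc <- ev$accuracy
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: Ld %.4f Lc %.4f trainAcc %s valAcc %s",
                      ep, row$Ld, row$Lc,
                      ifelse(is.na(row$trainAcc), "-",
                             sprintf("%.3f", row$trainAcc)),
                      ifelse(is.na(row$valAcc), "-",
                             sprintf("%.3f", row$valAcc))))
  }
  model$history <- hist
  model
}

#' Evaluate the autoencoder on a dataset
#'
#' Runs the load-time pipeline (configurably) and the forward pass in
#' batches; reports the loss components, exact-match accuracy, and the
#' denoising comparison (MSE of the denoised vs the noisy input against the
#' ground truth, both in normalized units).
#'
#' @param model a trained model.
#' @param data dataset list (see \code{\link{trainAE}}).
#' @param addNoise,augment load-time pipeline switches.
#' @param batch evaluation batch size.
#' @param engine forward-pass implementation, as in \code{\link{trainAE}}.
#' @return list with \code{accuracy}, \code{Ld}, \code{Lc}, \code{yHat},
#'   \code{probs}, \code{mseDenoised}, \code{mseInput}, \code{maeNm}.
#' @export
evalAE <- function(model, data, addNoise = FALSE, augment = FALSE,
                   batch = 256L, engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  n <- nrow(data$gt)
  probs <- matrix(0, n, model$cfg$nStates)
  Ld <- 0; mseIn <- 0; maeNm <- 0
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch - 1L, n)
    bt <- .makeBatch(data, idx, augment, addNoise)
    if (engine == "compiled") {
      pr <- .cpp_ae_predict(model$params, model$cfg, bt$noisy01, FALSE)
      fwd <- list(out01 = pr$out01, logits = pr$logits)
      probs[idx, ] <- pr$probs
    } else {
      fwd <- .forwardAE(model, bt$noisy01)
      probs[idx, ] <- .softmaxRows(fwd$logits)
    }
    Ld <- Ld + sum((bt$gt01 - fwd$out01)^2) / ncol(bt$gt01)
    mseIn <- mseIn + sum((bt$gt01 - bt$noisy01)^2) / ncol(bt$gt01)
    rngs <- bt$vmax - bt$vmin
    denNm <- fwd$out01 * rngs + bt$vmin
    gtNm <- bt$gt01 * rngs + bt$vmin
    maeNm <- maeNm + sum(abs(denNm - gtNm)) / ncol(bt$gt01)
    i <- i + batch
  }
  yHat <- max.col(probs, ties.method = "first")
  pick <- probs[cbind(seq_len(n), data$state)]
  list(accuracy = mean(yHat == data$state),
       Ld = Ld / n, Lc = mean(-log(pmax(pick, 1e-12))),
       yHat = yHat, probs = probs,
       mseDenoised = Ld / n, mseInput = mseIn / n, maeNm = maeNm / n)
}

#' Denoise and classify one height image
#'
#' Normalizes the image by its own min/max, runs the forward pass, and
#' rescales the denoised output back to nm with the input's extrema.
#'
#' @param model a trained model.
#' @param img a \linkS4class{HeightImage} (nm) on the model's pixel grid.
#' @return list with \code{probs}, \code{stateHat}, \code{denoised01},
#'   \code{denoisedNm} (a \linkS4class{HeightImage}) and \code{rollout}
#'   (attention rollout map in [0, 1]).
#' @export
inferAE <- function(model, img) {
  stopifnot(is(img, "HeightImage"))
  side <- model$cfg$imagePx
  if (!all(dim(img@values) == side))
    stop("image must be ", side, " x ", side, " pixels (preprocess first)")
  nrm <- minmaxNormalize(img)
  pr <- .cpp_ae_predict(model$params, model$cfg,
                        matrix(as.numeric(nrm$values01), 1L), TRUE)
  probs <- as.numeric(pr$probs)
  den01 <- matrix(pr$out01[1L, ], side, side)
  denNm <- minmaxRescale(den01, nrm$vmin, nrm$vmax, img@grid)
  list(probs = probs, stateHat = which.max(probs), denoised01 = den01,
       denoisedNm = denNm,
       rollout = .rolloutFromAtt(model$cfg, c(pr$attEnc, pr$attCls)))
}

## rollout from a list of head-averaged T x T attention matrices
.rolloutFromAtt <- function(cfg, attList) {
  Tn <- cfg$nPatch + 1L
  M <- diag(Tn)
  for (A in attList) {
    A <- 0.5 * (A + diag(Tn))   # blend in the residual path
    A <- A / rowSums(A)
    M <- A %*% M
  }
  v <- M[1L, -1L]                      # class-token row over patch tokens
  nSide <- cfg$imagePx %/% cfg$patchPx
  m <- matrix(v, nSide, nSide, byrow = TRUE)  # patch grid, row-major
  up <- kronecker(m, matrix(1, cfg$patchPx, cfg$patchPx))
  if (max(up) > min(up)) return((up - min(up)) / (max(up) - min(up)))
  # degenerate uniform map (e.g. identity attention): constant in [0, 1]
  matrix(as.numeric(up[1L] > 0), nrow(up), ncol(up))
}

#' Attention rollout map for an image
#'
#' Per attention layer the head-averaged attention matrix is blended with
#' the identity (0.5 * (A + I), accounting for the residual path),
#' row-renormalized, and the per-layer matrices are multiplied; the
#' class-token row of the product, reshaped to the patch grid and upsampled
#' to pixels, shows where the classification looked. Spans the encoder and
#' classifier layers by default.
#'
#' @param model a model.
#' @param img a \linkS4class{HeightImage} on the model grid.
#' @param span \code{"both"}, \code{"encoder"} or \code{"classifier"}.
#' @return imagePx x imagePx matrix normalized to [0, 1].
#' @export
attentionRollout <- function(model, img, span = c("both", "encoder",
                                                  "classifier")) {
  span <- match.arg(span)
  nrm <- minmaxNormalize(img)
  pr <- .cpp_ae_predict(model$params, model$cfg,
                        matrix(as.numeric(nrm$values01), 1L), TRUE)
  attList <- switch(span, encoder = pr$attEnc, classifier = pr$attCls,
                    both = c(pr$attEnc, pr$attCls))
  .rolloutFromAtt(model$cfg, attList)
}

#' Initialize a model from pretrained weights (transfer learning)
#'
#' Copies every tensor whose name and shape match from the source model
#' into a freshly initialized target; the classifier output layer is left
#' at its fresh initialization when the state count differs. Optionally
#' freezes the encoder (embedding + encoder blocks are then excluded from
#' optimization).
#'
#' @param src a trained model (or loaded checkpoint).
#' @param cfgNew target \code{\link{modelConfig}}; defaults to the source
#'   configuration (so only e.g. \code{nStates} changes).
#' @param freezeEncoder freeze embedding and encoder weights.
#' @param seed initialization seed for non-copied tensors.
#' @return a model object.
#' @export
transferInit <- function(src, cfgNew = NULL, freezeEncoder = FALSE,
                         seed = 1L) {
  cfgNew <- cfgNew %||% src$cfg
  target <- buildModel(cfgNew, seed = seed)
  copied <- character(0)
  for (nm in names(target$params)) {
    s <- src$params[[nm]]
    if (!is.null(s) && identical(dim(s), dim(target$params[[nm]])) &&
        length(s) == length(target$params[[nm]])) {
      target$params[[nm]] <- s
      copied <- c(copied, nm)
    }
  }
  if (freezeEncoder)
    target$freeze <- grep("^(embed|enc)", names(target$params), value = TRUE)
  target$copied <- copied
  target
}

#' Save / load a model checkpoint
#'
#' The weights go into an RDS container, with a JSON sidecar holding the
#' architecture and training configuration, the state count, the
#' normalization convention and library versions.
#'
#' @param model a model.
#' @param dir checkpoint directory (created if needed).
#' @return \code{dir} (save) or the model (load).
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(cfg = model$cfg, freeze = model$freeze,
               normalization = "minmax-by-input",
               package = as.character(utils::packageVersion("afmstate")),
               r_version = as.character(getRversion()))
  jsonlite::write_json(meta, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "checkpoint.json"),
                              simplifyVector = TRUE)
  cfg <- meta$cfg
  cfg[c("nStates", "imagePx", "patchPx", "encLayers", "encDim", "decLayers",
        "decDim", "clsLayers", "heads", "mlpRatio", "nPatch")] <-
    lapply(cfg[c("nStates", "imagePx", "patchPx", "encLayers", "encDim",
                 "decLayers", "decDim", "clsLayers", "heads", "mlpRatio",
                 "nPatch")], as.integer)
  model <- list(params = readRDS(file.path(dir, "weights.rds")), cfg = cfg,
                freeze = as.character(meta$freeze %||% character(0)))
  hPath <- file.path(dir, "history.csv")
  if (file.exists(hPath)) model$history <- utils::read.csv(hPath)
  model
}
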