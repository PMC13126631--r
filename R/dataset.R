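## Paired-image dataset production and loading.
##
## A dataset is a set of sharded POSIX tar archives; each sample contributes
## three members named <key>.gt.tiff (noise-free render), <key>.noisy.tiff
## (scan-lag distorted render) and <key>.json (state label and generation
## parameters), with zero-padded keys so streaming loaders group them. The
## scan-lag distortion is baked in at build time; additive white noise and
## the +/-3 px augmentation shift are applied at load time, so one stored
## dataset serves many noise levels. Min-max normalization of *both* images
## of a pair uses the noisy input's min/max — the quantities available at
## inference time, which the denoiser output is rescaled by.

#' Min-max normalize an image
#'
#' @param img a \linkS4class{HeightImage} or numeric matrix.
#' @return list with \code{values01} (matrix in [0, 1]), \code{vmin} and
#'   \code{vmax} (nm). A constant image maps to all zeros with
#'   \code{vmin == vmax} recorded.
#' @export
minmaxNormalize <- function(img) {
  v <- if (is(img, "HeightImage")) img@values else img
  vmin <- min(v); vmax <- max(v)
  if (vmax > vmin) v01 <- (v - vmin) / (vmax - vmin)
  else v01 <- matrix(0, nrow(v), ncol(v))
  list(values01 = v01, vmin = vmin, vmax = vmax)
}

#' Invert min-max normalization
#'
#' @param values01 normalized matrix.
#' @param vmin,vmax the recorded extrema in nm.
#' @param grid optional \linkS4class{ImageGrid} for the result.
#' @return a \linkS4class{HeightImage} in nm.
#' @export
minmaxRescale <- function(values01, vmin, vmax, grid = NULL) {
  stopifnot(vmax >= vmin)
  HeightImage(values01 * (vmax - vmin) + vmin,
              grid %||% ImageGrid(nx = ncol(values01), ny = nrow(values01)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.keyFormat <- function(i) sprintf("%010d", i)

#' Build a sharded training dataset
#'
#' Draws frames uniformly from the ensemble; per pair samples a tip and
#' initial pose from the parameter grids, renders the ground-truth image and
#' the scan-lag-distorted image, records a white-noise level sigma_N
#' (deferred to load time), and writes the pairs to tar shards. Generation
#' is deterministic given (seed, shard index): each shard uses its own
#' derived substream, so shards can be produced independently.
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param sm a completed \linkS4class{StateModel} labelling the frames.
#' @param nPairs number of pairs to generate.
#' @param dir output directory for \code{shard-NNNN.tar} files.
#' @param ranges parameter grids from \code{\link{simParamRanges}}.
#' @param noise a \linkS4class{ScanNoiseParams}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param shardSize pairs per archive.
#' @param seed master seed.
#' @param sigmaRange white-noise grid limits (nm), see
#'   \code{\link{sampleSigmaN}}.
#' @return character vector of shard paths, invisibly.
#' @export
buildDataset <- function(ens, sm, nPairs, dir, ranges = simParamRanges(),
                         noise = ScanNoiseParams(), grid = ImageGrid(),
                         shardSize = 1000L, seed = 1L,
                         sigmaRange = c(0, 0.3)) {
  stopifnot(nPairs >= 1L, shardSize >= 1L)
  if (sm@K == 0L) stop("state model has no states")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nShards <- ceiling(nPairs / shardSize)
  shardPaths <- character(nShards)
  for (s in seq_len(nShards)) {
    first <- (s - 1L) * shardSize
    nHere <- min(shardSize, nPairs - first)
    set.seed(deriveSeed(seed, paste0("shard", s)))
    staging <- tempfile("shard")
    dir.create(staging)
    files <- character(0)
    for (j in seq_len(nHere)) {
      key <- .keyFormat(first + j - 1L)
      frame <- sample.int(nConformers(ens), 1L)
      par <- sampleSimParams(ranges)
      sigmaN <- sampleSigmaN(sigmaRange[1L], sigmaRange[2L])
      gt <- renderImage(ens[[frame]], par$pose, par$tip, grid)
      noisy <- renderWithScanLag(ens[[frame]], par$pose, par$tip, grid, noise)
      fGt <- file.path(staging, paste0(key, ".gt.tiff"))
      fNo <- file.path(staging, paste0(key, ".noisy.tiff"))
      fJs <- file.path(staging, paste0(key, ".json"))
      writeHeightImage(gt, fGt)
      writeHeightImage(noisy, fNo)
      jsonlite::write_json(list(
        key = key, state = sm@labels[frame], frame_id = ens@frameIds[frame],
        R = par$tip@radius, Theta = par$tip@halfAngle,
        pose0 = as.list(poseVector(par$pose)), sigma_N = sigmaN,
        seed = seed, shard = s), fJs, auto_unbox = TRUE, digits = NA)
      files <- c(files, fGt, fNo, fJs)
    }
    Sys.setFileTime(files, as.POSIXct("2000-01-01", tz = "UTC"))
    shardPaths[s] <- file.path(normalizePath(dir),
                               sprintf("shard-%04d.tar", s - 1L))
    od <- setwd(staging)
    tryCatch(utils::tar(shardPaths[s], files = basename(files),
                        tar = "internal"),
             finally = setwd(od))
    unlink(staging, recursive = TRUE)
  }
  invisible(shardPaths)
}

#' Generate training pairs in memory
#'
#' Same sampling scheme as \code{\link{buildDataset}} (uniform frames,
#' gridded tip/pose parameters, scan-lag noisy member, recorded sigma_N)
#' but returning the dataset list directly instead of writing tar shards —
#' convenient at desk scale where the whole set fits in memory.
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param labels integer state label per frame.
#' @param nPairs number of pairs.
#' @param ranges parameter grids from \code{\link{simParamRanges}}.
#' @param noise a \linkS4class{ScanNoiseParams}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param seed RNG seed.
#' @param sigmaRange white-noise grid limits in nm.
#' @return dataset list (\code{gt}, \code{noisy}, \code{state},
#'   \code{sigmaN}, \code{frame}, \code{dim}) as from
#'   \code{\link{readDataset}}.
#' @export
makeTrainingPairs <- function(ens, labels, nPairs, ranges = simParamRanges(),
                              noise = ScanNoiseParams(), grid = ImageGrid(),
                              seed = 1L, sigmaRange = c(0, 0.3)) {
  set.seed(deriveSeed(seed, "pairs"))
  np <- grid@nx * grid@ny
  gt <- matrix(0, nPairs, np)
  noisy <- matrix(0, nPairs, np)
  state <- integer(nPairs)
  sigmaN <- numeric(nPairs)
  frame <- integer(nPairs)
  for (i in seq_len(nPairs)) {
    f <- sample.int(nConformers(ens), 1L)
    par <- sampleSimParams(ranges)
    sigmaN[i] <- sampleSigmaN(sigmaRange[1L], sigmaRange[2L])
    gt[i, ] <- as.numeric(
      renderImage(ens[[f]], par$pose, par$tip, grid)@values)
    noisy[i, ] <- as.numeric(
      renderWithScanLag(ens[[f]], par$pose, par$tip, grid, noise)@values)
    state[i] <- labels[f]
    frame[i] <- f
  }
  list(gt = gt, noisy = noisy, state = state, sigmaN = sigmaN,
       frame = frame, dim = c(grid@ny, grid@nx))
}

.readShardSamples <- function(shard) {
  ex <- tempfile("unshard")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE))
  utils::untar(shard, exdir = ex, tar = "internal")
  jsons <- sort(list.files(ex, pattern = "\\.json$", full.names = TRUE))
  out <- vector("list", length(jsons))
  nOk <- 0L; nBad <- 0L
  for (f in jsons) {
    key <- sub("\\.json$", "", basename(f))
    smp <- tryCatch({
      meta <- jsonlite::read_json(f, simplifyVector = TRUE)
      gt <- readHeightImage(file.path(ex, paste0(key, ".gt.tiff")))
      noisy <- readHeightImage(file.path(ex, paste0(key, ".noisy.tiff")))
      list(key = key, meta = meta, gt = gt@values, noisy = noisy@values)
    }, error = function(e) NULL)
    if (is.null(smp)) { nBad <- nBad + 1L; next }
    nOk <- nOk + 1L
    out[[nOk]] <- smp
  }
  if (nBad > 0L)
    warning(nBad, " corrupt sample(s) skipped in ", basename(shard))
  out[seq_len(nOk)]
}

#' Load a whole dataset into memory
#'
#' Reads every pair of every shard (images in nm, no load-time transforms).
#' Convenient at desk scale; use \code{\link{streamBatches}} for datasets
#' that do not fit in memory.
#'
#' @param archives shard paths, or a directory containing \code{shard-*.tar}.
#' @return list with matrices \code{gt} and \code{noisy} (one row per sample,
#'   pixels in scan order), \code{state}, \code{sigmaN}, \code{keys} and
#'   \code{dim} (image size).
#' @export
readDataset <- function(archives) {
  if (length(archives) == 1L && dir.exists(archives))
    archives <- sort(list.files(archives, pattern = "^shard-.*\\.tar$",
                                full.names = TRUE))
  samples <- unlist(lapply(archives, .readShardSamples), recursive = FALSE)
  if (length(samples) == 0L) stop("no samples found")
  d <- dim(samples[[1L]]$gt)
  list(
    gt = t(vapply(samples, function(s) as.numeric(s$gt), numeric(prod(d)))),
    noisy = t(vapply(samples, function(s) as.numeric(s$noisy), numeric(prod(d)))),
    state = vapply(samples, function(s) as.integer(s$meta$state), integer(1)),
    sigmaN = vapply(samples, function(s) as.numeric(s$meta$sigma_N), numeric(1)),
    keys = vapply(samples, function(s) s$key, character(1)),
    dim = d)
}

## Load-time transform of one pair: optional joint +/-maxShift pixel shift,
## white noise on the noisy member at its recorded sigma_N, then min-max
## normalization of both members by the noisy member's extrema.
.loadTransform <- function(gt, noisy, sigmaN, augment, maxShift = 3L,
                           addNoise = TRUE) {
  if (augment) {
    sft <- sample.int(2L * maxShift + 1L, 2L, replace = TRUE) - maxShift - 1L
    gt <- .shiftMatrix(gt, sft[1L], sft[2L])
    noisy <- .shiftMatrix(noisy, sft[1L], sft[2L])
  }
  if (addNoise && sigmaN > 0)
    noisy <- noisy + rnorm(length(noisy), 0, sigmaN)
  vmin <- min(noisy); vmax <- max(noisy)
  rng <- vmax - vmin
  if (rng > 0) {
    noisy01 <- (noisy - vmin) / rng
    gt01 <- (gt - vmin) / rng
  } else {
    noisy01 <- noisy * 0
    gt01 <- gt * 0
  }
  list(noisy01 = noisy01, gt01 = gt01, vmin = vmin, vmax = vmax)
}

#' Stream normalized training batches from shard archives
#'
#' Returns a generator: each call to \code{nextBatch()} yields a list with
#' \code{noisy01} and \code{gt01} (batch x pixels matrices), \code{state},
#' \code{vmin}, \code{vmax}, or \code{NULL} when the pass is complete.
#' Samples are read shard by shard and shuffled within a bounded buffer, so
#' memory stays O(batch + buffer). \code{reset()} starts a new pass (with a
#' fresh shuffle).
#'
#' @param archives shard paths or a dataset directory.
#' @param batchSize samples per batch.
#' @param augment apply the joint +/-3 px shift.
#' @param addNoise add white noise at each sample's recorded sigma_N.
#' @param shuffle shuffle within the buffer (and shard order per pass).
#' @param bufferSize shuffle buffer size in samples.
#' @param seed RNG seed for shuffling/augmentation.
#' @return list of functions \code{nextBatch} and \code{reset}.
#' @export
streamBatches <- function(archives, batchSize = 32L, augment = TRUE,
                          addNoise = TRUE, shuffle = TRUE,
                          bufferSize = 2000L, seed = 1L) {
  if (length(archives) == 1L && dir.exists(archives))
    archives <- sort(list.files(archives, pattern = "^shard-.*\\.tar$",
                                full.names = TRUE))
  env <- new.env()
  reset <- function() {
    set.seed(deriveSeed(seed, "stream"))
    env$order <- if (shuffle) sample(seq_along(archives)) else seq_along(archives)
    env$nextShard <- 1L
    env$buffer <- list()
    invisible(NULL)
  }
  fill <- function() {
    while (length(env$buffer) < bufferSize &&
           env$nextShard <= length(archives)) {
      smp <- .readShardSamples(archives[env$order[env$nextShard]])
      env$nextShard <- env$nextShard + 1L
      env$buffer <- c(env$buffer, smp)
    }
  }
  nextBatch <- function() {
    fill()
    if (length(env$buffer) == 0L) return(NULL)
    take <- min(batchSize, length(env$buffer))
    idx <- if (shuffle) sample.int(length(env$buffer), take) else seq_len(take)
    picked <- env$buffer[idx]
    env$buffer <- env$buffer[-idx]
    np <- length(picked[[1L]]$gt)
    noisy01 <- matrix(0, take, np); gt01 <- matrix(0, take, np)
    state <- integer(take); vmin <- numeric(take); vmax <- numeric(take)
    for (i in seq_len(take)) {
      s <- picked[[i]]
      tr <- .loadTransform(s$gt, s$noisy, s$meta$sigma_N, augment,
                           addNoise = addNoise)
      noisy01[i, ] <- as.numeric(tr$noisy01)
      gt01[i, ] <- as.numeric(tr$gt01)
      state[i] <- as.integer(s$meta$state)
      vmin[i] <- tr$vmin; vmax[i] <- tr$vmax
    }
    list(noisy01 = noisy01, gt01 = gt01, state = state,
         vmin = vmin, vmax = vmax,
         keys = vapply(picked, function(s) s$key, character(1)))
  }
  reset()
  list(nextBatch = nextBatch, reset = reset)
}
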