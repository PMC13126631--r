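## Line-scan temporal lag emulation.
##
## An HS-AFM frame is acquired line by line along the fast (x) axis. Between
## lines the molecule diffuses, so each scan line effectively sees the
## molecule at a slightly different lateral position and orientation. Per
## line a perturbation of the initial pose is drawn from truncated zero-mean
## normals (displacements are taken from the t = 0 pose, not accumulated),
## the line is rendered with the perturbed pose, and the lines are assembled
## into one distorted image. The internal conformation is held fixed.

#' Draw one line perturbation
#'
#' Components are sampled from N(0, s * var_i). Truncation is enforced by
#' rejection resampling (which preserves the normal shape inside the
#' admissible region and tends to the uniform distribution on it as
#' s grows large): (dx, dy) are redrawn jointly until
#' sqrt(dx^2 + dy^2) <= w * drMax, each angle independently until within its
#' bound. s = 0 or w = 0 short-circuits to the zero perturbation.
#'
#' @param p a \linkS4class{ScanNoiseParams}.
#' @return named numeric (dx, dy, dphi, dtheta, dpsi) in nm / deg.
#' @export
sampleLinePerturbation <- function(p = ScanNoiseParams()) {
  stopifnot(is(p, "ScanNoiseParams"))
  zero <- c(dx = 0, dy = 0, dphi = 0, dtheta = 0, dpsi = 0)
  if (p@s == 0 || p@w == 0) return(zero)
  sdx <- sqrt(p@s * p@varX); sdy <- sqrt(p@s * p@varY)
  repeat {
    dx <- rnorm(1L, 0, sdx); dy <- rnorm(1L, 0, sdy)
    if (sqrt(dx * dx + dy * dy) <= p@w * p@drMax) break
  }
  drawAngle <- function(var, bound) {
    if (var == 0) return(0)
    sdv <- sqrt(p@s * var)
    repeat {
      a <- rnorm(1L, 0, sdv)
      if (abs(a) <= p@w * bound) return(a)
    }
  }
  c(dx = dx, dy = dy,
    dphi = drawAngle(p@varPhi, p@dphiMax),
    dtheta = drawAngle(p@varTheta, p@dthetaMax),
    dpsi = drawAngle(p@varPsi, p@dpsiMax))
}

#' Draw many line perturbations at once
#'
#' Vectorized version of \code{\link{sampleLinePerturbation}} (batched
#' rejection resampling); used for distributional checks at large n.
#'
#' @param n number of draws.
#' @param p a \linkS4class{ScanNoiseParams}.
#' @return n x 5 matrix with columns dx, dy, dphi, dtheta, dpsi.
#' @export
sampleLinePerturbations <- function(n, p = ScanNoiseParams()) {
  stopifnot(is(p, "ScanNoiseParams"), n >= 1L)
  out <- matrix(0, n, 5L,
                dimnames = list(NULL, c("dx", "dy", "dphi", "dtheta", "dpsi")))
  if (p@s == 0 || p@w == 0) return(out)
  rejNorm2 <- function(n, sd1, sd2, bound) {
    a <- rnorm(n, 0, sd1); b <- rnorm(n, 0, sd2)
    repeat {
      bad <- which(sqrt(a^2 + b^2) > bound)
      if (!length(bad)) return(cbind(a, b))
      a[bad] <- rnorm(length(bad), 0, sd1)
      b[bad] <- rnorm(length(bad), 0, sd2)
    }
  }
  rejNorm1 <- function(n, sd, bound) {
    if (sd == 0) return(numeric(n))
    x <- rnorm(n, 0, sd)
    repeat {
      bad <- which(abs(x) > bound)
      if (!length(bad)) return(x)
      x[bad] <- rnorm(length(bad), 0, sd)
    }
  }
  out[, 1:2] <- rejNorm2(n, sqrt(p@s * p@varX), sqrt(p@s * p@varY),
                         p@w * p@drMax)
  out[, 3L] <- rejNorm1(n, sqrt(p@s * p@varPhi), p@w * p@dphiMax)
  out[, 4L] <- rejNorm1(n, sqrt(p@s * p@varTheta), p@w * p@dthetaMax)
  out[, 5L] <- rejNorm1(n, sqrt(p@s * p@varPsi), p@w * p@dpsiMax)
  out
}

.perturbPose <- function(pose0, d) {
  Pose(x = pose0@x + d[["dx"]], y = pose0@y + d[["dy"]],
       phi = pose0@phi + d[["dphi"]], theta = pose0@theta + d[["dtheta"]],
       psi = pose0@psi + d[["dpsi"]])
}

#' Render an image with line-scan lag distortion
#'
#' Lines are rendered bottom row to top row, pixels left to right. Each line
#' draws its own independent perturbation of the initial pose (including the
#' first line). With s = 0 or w = 0 the result is bit-identical to
#' \code{\link{renderImage}}.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param pose0 initial \linkS4class{Pose} (the t = 0 reference).
#' @param tip a \linkS4class{TipModel}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param p a \linkS4class{ScanNoiseParams}.
#' @param stage stage-height convention, see \code{\link{transformModel}}.
#' @param returnPerturbations also return the ny x 5 matrix of per-line
#'   perturbations (for replay/diagnostics).
#' @return A \linkS4class{HeightImage}, or a list
#'   \code{(image, perturbations)} if requested.
#' @export
renderWithScanLag <- function(model, pose0 = Pose(), tip = TipModel(),
                              grid = ImageGrid(), p = ScanNoiseParams(),
                              stage = "surface", returnPerturbations = FALSE) {
  vals <- matrix(0, grid@ny, grid@nx)
  pert <- matrix(0, grid@ny, 5L,
                 dimnames = list(NULL, c("dx", "dy", "dphi", "dtheta", "dpsi")))
  for (i in seq_len(grid@ny)) {
    d <- sampleLinePerturbation(p)
    pert[i, ] <- d
    vals[i, ] <- .renderPosedRows(model, .perturbPose(pose0, d), tip, grid,
                                  i, stage)
  }
  img <- HeightImage(vals, grid)
  if (returnPerturbations) list(image = img, perturbations = pert) else img
}

#' Add pixelwise Gaussian white noise
#'
#' Measurement noise: independent N(0, sigmaN^2) added to every pixel, with
#' no clamping (negative heights are permitted, as in real recordings).
#'
#' @param img a \linkS4class{HeightImage}.
#' @param sigmaN noise standard deviation in nm (>= 0).
#' @return A \linkS4class{HeightImage}.
#' @export
addWhiteNoise <- function(img, sigmaN) {
  stopifnot(is(img, "HeightImage"))
  if (!is.finite(sigmaN) || sigmaN < 0) stop("sigmaN must be >= 0")
  if (sigmaN == 0) return(img)
  v <- img@values + rnorm(length(img@values), 0, sigmaN)
  HeightImage(matrix(v, nrow(img@values), ncol(img@values)), img@grid)
}

#' Draw a white-noise level from the training grid
#'
#' Uniform over the inclusive grid \code{seq(lo, hi, by = step)}; the default
#' 0.0-0.3 nm in 0.01 nm steps spans the realistic vertical-noise range of
#' HS-AFM.
#'
#' @param lo,hi,step grid limits and step in nm.
#' @return a single sigma_N value in nm.
#' @export
sampleSigmaN <- function(lo = 0.0, hi = 0.3, step = 0.01) {
  if (lo > hi || step <= 0) stop("need lo <= hi and step > 0")
  g <- seq(lo, hi, by = step)
  g[sample.int(length(g), 1L)]
}

#' Shift a ground-truth/noisy image pair by a random whole-pixel offset
#'
#' One integer shift (dx, dy) is drawn uniformly from the
#' \code{[-maxShift, maxShift]^2} square and applied identically to both
#' images; vacated pixels are zero-filled. Used as training-time
#' augmentation to randomize the molecule's lateral position.
#'
#' @param gt,noisy \linkS4class{HeightImage}s on one grid.
#' @param maxShift maximum |shift| per axis in pixels.
#' @return list \code{(gt, noisy, shift)} with \code{shift = c(dx, dy)}.
#' @export
randomPixelShift <- function(gt, noisy, maxShift = 3L) {
  stopifnot(identical(dim(gt@values), dim(noisy@values)))
  if (maxShift >= min(dim(gt@values))) stop("shift larger than image")
  sft <- sample.int(2L * maxShift + 1L, 2L, replace = TRUE) - maxShift - 1L
  list(gt = shiftImage(gt, sft[1L], sft[2L]),
       noisy = shiftImage(noisy, sft[1L], sft[2L]),
       shift = sft)
}

#' Translate an image by whole pixels with zero fill
#'
#' @param img a \linkS4class{HeightImage}.
#' @param dx shift along +x in pixels (columns).
#' @param dy shift along +y in pixels (rows).
#' @return the shifted \linkS4class{HeightImage}.
#' @export
shiftImage <- function(img, dx, dy) {
  HeightImage(.shiftMatrix(img@values, dx, dy), img@grid)
}

.shiftMatrix <- function(v, dx, dy) {
  ny <- nrow(v); nx <- ncol(v)
  if (abs(dx) >= nx || abs(dy) >= ny) stop("shift larger than image")
  out <- matrix(0, ny, nx)
  rs <- seq_len(ny) - dy  # source rows
  cs <- seq_len(nx) - dx
  okR <- rs >= 1L & rs <= ny
  okC <- cs >= 1L & cs <= nx
  out[which(okR), which(okC)] <- v[rs[okR], cs[okC], drop = FALSE]
  out
}
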