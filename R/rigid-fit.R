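## Rigid-body fitting by exhaustive grid search.
##
## Candidate structures (typically the K state centers) are rendered at
## every grid point of (psi, phi, theta, R, Theta), each render is slid over
## the reference image by integer pixel shifts (zero fill), and the
## candidate/pose with the highest pixel Pearson correlation wins. The
## search order and strict-improvement argmax make ties break
## deterministically toward the lowest state and earliest grid point.

#' Pixel correlation coefficient of two images
#'
#' Pearson correlation over all pixels; invariant to affine intensity
#' transforms (a * I + b with a > 0) of either image.
#'
#' @param sim,ref \linkS4class{HeightImage}s (or matrices) on one grid.
#' @return correlation in [-1, 1].
#' @export
ccScore <- function(sim, ref) {
  a <- if (is(sim, "HeightImage")) sim@values else sim
  b <- if (is(ref, "HeightImage")) ref@values else ref
  stopifnot(identical(dim(a), dim(b)))
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da * da); vb <- sum(db * db)
  if (va == 0 || vb == 0)
    stop("correlation undefined: constant image")
  sum(da * db) / sqrt(va * vb)
}

#' Search grid for rigid-body fitting
#'
#' The reference grid spans psi in [-180, 180] deg in 5 deg steps and
#' phi, theta in [-30, 30] deg in 5 deg steps, with the probe fixed at
#' R = 1 nm, Theta = 10 deg (gridded probe parameters are used for
#' experimental images where the probe is unknown), and a +/-3 px lateral
#' shift search.
#'
#' @param psi,phi,theta numeric vectors of angles (deg).
#' @param R,Theta numeric vectors of probe parameters (nm, deg).
#' @param shiftPx maximum |pixel shift| per axis.
#' @return a FitGrid list.
#' @export
fitGrid <- function(psi = seq(-180, 180, by = 5),
                    phi = seq(-30, 30, by = 5),
                    theta = seq(-30, 30, by = 5),
                    R = 1, Theta = 10, shiftPx = 3L) {
  stopifnot(length(psi) > 0, length(phi) > 0, length(theta) > 0,
            length(R) > 0, length(Theta) > 0, shiftPx >= 0L)
  list(psi = psi, phi = phi, theta = theta, R = R, Theta = Theta,
       shiftPx = as.integer(shiftPx))
}

#' Fit candidate structures to an image by exhaustive grid search
#'
#' @param image reference \linkS4class{HeightImage}.
#' @param candidates list of \linkS4class{BeadModel}s (e.g. state centers).
#' @param grid a \code{\link{fitGrid}}.
#' @param stage stage-height convention (see \code{\link{transformModel}}).
#' @param topN size of the returned score table.
#' @return a \linkS4class{FitResult}.
#' @export
rigidFit <- function(image, candidates, grid = fitGrid(),
                     stage = "surface", topN = 10L) {
  stopifnot(is(image, "HeightImage"), length(candidates) >= 1L)
  g <- image@grid
  res <- .cpp_rigid_fit(
    lapply(candidates, coords), lapply(candidates, radii), image@values,
    grid$psi, grid$phi, grid$theta, grid$R, grid$Theta,
    grid$shiftPx, g@pixelSize, g@origin[1L], g@origin[2L],
    identical(stage, "surface"), as.integer(topN))
  top <- data.frame(
    state = res$topIdx[, 1L] + 1L,
    psi = grid$psi[res$topIdx[, 2L] + 1L],
    phi = grid$phi[res$topIdx[, 3L] + 1L],
    theta = grid$theta[res$topIdx[, 4L] + 1L],
    R = grid$R[res$topIdx[, 5L] + 1L],
    Theta = grid$Theta[res$topIdx[, 6L] + 1L],
    sx = res$topIdx[, 7L], sy = res$topIdx[, 8L],
    cc = res$topCC)
  new("FitResult",
      state = as.integer(res$state),
      pose = Pose(phi = grid$phi[res$iPhi], theta = grid$theta[res$iTheta],
                  psi = grid$psi[res$iPsi]),
      tip = TipModel(radius = grid$R[res$iR], halfAngle = grid$Theta[res$iT]),
      shift = as.integer(c(res$sx, res$sy)),
      cc = res$cc, table = top)
}

#' Rigid-body fitting after denoising and state assignment
#'
#' Runs the trained autoencoder on the image, restricts the candidate list
#' to the predicted state's center, and fits the pose only. Fitting the
#' denoised output rather than the raw image avoids the noise-overfitting
#' that plagues direct correlation fitting.
#'
#' @param image raw \linkS4class{HeightImage}.
#' @param model a trained autoencoder.
#' @param candidates list of state-center \linkS4class{BeadModel}s, indexed
#'   by state.
#' @param grid a \code{\link{fitGrid}}.
#' @param fitDenoised fit the denoised image (default) or the raw input.
#' @param ... passed to \code{\link{rigidFit}}.
#' @return a \linkS4class{FitResult} whose \code{state} slot is the
#'   autoencoder's assignment; the attribute \code{"prediction"} carries the
#'   full \code{\link{inferAE}} output.
#' @export
fitAfterDenoise <- function(image, model, candidates, grid = fitGrid(),
                            fitDenoised = TRUE, ...) {
  pred <- inferAE(model, image)
  target <- if (fitDenoised) pred$denoisedNm else image
  res <- rigidFit(target, candidates[pred$stateHat], grid, ...)
  res@state <- as.integer(pred$stateHat)
  attr(res, "prediction") <- pred
  res
}
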