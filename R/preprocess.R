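## Experimental image preprocessing.
##
## Raw HS-AFM recordings of a molecule on a support lattice are converted to
## model-ready inputs: the stage level is estimated from lattice pixels
## (excluding both lattice holes and the molecule), holes are filled with
## that level, the mean height is subtracted, the molecule is re-centered by
## an integer shift, and the frame is cropped or zero-padded to the model's
## working size. Heights stay in nm end to end.

#' Automatic hole and molecule masks
#'
#' Robust threshold masks for images where masks were not recorded: pixels
#' below \code{median - k * MAD} are holes, pixels above
#' \code{median + k * MAD} the molecule.
#'
#' @param img a \linkS4class{HeightImage}.
#' @param k MAD multiplier (default 3).
#' @return list of logical matrices \code{hole} and \code{molecule}.
#' @export
autoMasks <- function(img, k = 3) {
  v <- img@values
  m <- median(v); s <- mad(v)
  list(hole = v < m - k * s, molecule = v > m + k * s)
}

#' Estimate the stage height
#'
#' Mean height over pixels that are neither holes nor molecule.
#'
#' @param img a \linkS4class{HeightImage}.
#' @param holeMask,moleculeMask logical matrices on the image grid.
#' @return stage height in nm.
#' @export
estimateStage <- function(img, holeMask, moleculeMask) {
  v <- img@values
  stopifnot(identical(dim(v), dim(holeMask)),
            identical(dim(v), dim(moleculeMask)))
  keep <- !(holeMask | moleculeMask)
  if (!any(keep)) stop("no lattice pixels left outside the masks")
  mean(v[keep])
}

#' Fill holes and level an image
#'
#' Hole pixels are replaced by the stage value, then the image mean is
#' subtracted from every pixel, so the output has mean zero.
#'
#' @param img a \linkS4class{HeightImage}.
#' @param holeMask logical matrix of hole pixels.
#' @param stage stage height in nm (from \code{\link{estimateStage}}).
#' @return a \linkS4class{HeightImage}.
#' @export
fillAndLevel <- function(img, holeMask, stage) {
  v <- img@values
  stopifnot(identical(dim(v), dim(holeMask)))
  v[holeMask] <- stage
  v <- v - mean(v)
  HeightImage(v, img@grid)
}

#' Center the molecule and standardize the frame size
#'
#' The intensity-weighted centroid of above-threshold pixels is moved to the
#' central pixel by an integer shift (zero fill), then the frame is
#' symmetrically cropped or zero-padded to \code{target x target} pixels.
#'
#' @param img a \linkS4class{HeightImage}.
#' @param target output edge in pixels (default 36).
#' @param threshold molecule threshold in nm; default half the image maximum.
#' @return a \linkS4class{HeightImage} of size target x target.
#' @export
centerAndFrame <- function(img, target = 36L, threshold = NULL) {
  v <- img@values
  if (is.null(threshold)) threshold <- max(v) / 2
  sel <- v > threshold
  if (!any(sel)) stop("no above-threshold pixel: cannot locate the molecule")
  w <- v * sel
  rows <- rowSums(w); cols <- colSums(w)
  ci <- sum(seq_along(rows) * rows) / sum(rows)
  cj <- sum(seq_along(cols) * cols) / sum(cols)
  di <- round((nrow(v) + 1) / 2 - ci)
  dj <- round((ncol(v) + 1) / 2 - cj)
  img <- shiftImage(img, dj, di)
  v <- img@values
  pad <- function(m, n) {
    cur <- dim(m)
    out <- matrix(0, n, n)
    ro <- floor((n - cur[1L]) / 2); co <- floor((n - cur[2L]) / 2)
    rs <- seq_len(min(cur[1L], n)); cs <- seq_len(min(cur[2L], n))
    srcR <- if (ro >= 0) rs else rs - ro
    srcC <- if (co >= 0) cs else cs - co
    dstR <- if (ro >= 0) rs + ro else rs
    dstC <- if (co >= 0) cs + co else cs
    out[dstR, dstC] <- m[srcR, srcC]
    out
  }
  out <- pad(v, as.integer(target))
  HeightImage(out, ImageGrid(nx = target, ny = target,
                             pixelSize = img@grid@pixelSize))
}

#' Full preprocessing pipeline
#'
#' \code{estimateStage} + \code{fillAndLevel} + \code{centerAndFrame} with
#' automatic masks unless masks are supplied. Idempotent for stable masks.
#'
#' @param img a \linkS4class{HeightImage}.
#' @param holeMask,moleculeMask optional logical matrices; derived by
#'   \code{\link{autoMasks}} when missing.
#' @param target output edge in pixels.
#' @return a \linkS4class{HeightImage}.
#' @export
preprocessImage <- function(img, holeMask = NULL, moleculeMask = NULL,
                            target = 36L) {
  if (is.null(holeMask) || is.null(moleculeMask)) {
    am <- autoMasks(img)
    if (is.null(holeMask)) holeMask <- am$hole
    if (is.null(moleculeMask)) moleculeMask <- am$molecule
  }
  stage <- estimateStage(img, holeMask, moleculeMask)
  centerAndFrame(fillAndLevel(img, holeMask, stage), target = target)
}
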