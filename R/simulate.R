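## Pseudo-AFM rendering by collision detection.
##
## The tip is a cone of half-apex angle Theta capped by a sphere of radius R
## (treated as infinitely tall: molecules are far shorter than real tips).
## For each pixel the tip descends vertically; the pixel height is the lowest
## tip-apex z at which the tip surface touches any bead, floored at 0 (the
## bare stage). For a bead at lateral distance d from the tip axis, contact
## is sphere-sphere when d <= (R + r) cos(Theta) and cone-flank beyond:
##   z = z_bead + sqrt((R + r)^2 - d^2) - R          (cap)
##   z = z_bead + (R + r - d cos(Theta))/sin(Theta) - R   (flank)
## The two branches agree at the crossover.

.rotZXY <- function(psi, phi, theta) {
  d <- pi / 180
  cz <- cos(psi * d); sz <- sin(psi * d)
  cx <- cos(phi * d); sx <- sin(phi * d)
  cy <- cos(theta * d); sy <- sin(theta * d)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Ry %*% Rx %*% Rz  # extrinsic z, then x, then y
}

#' Pose a bead model on the stage
#'
#' Rotates the model about its centroid sequentially about the fixed z-, x-
#' and y-axes (by psi, phi, theta), translates laterally by (x, y), and
#' applies the stage-height convention: the model is shifted along z so that
#' its minimum z-coordinate becomes 0. With \code{stage = "surface"} (the
#' default) the minimum is taken over bead surfaces (center z minus radius),
#' so spheres rest on the stage; \code{stage = "center"} uses bead centers,
#' the literal minimum-coordinate convention, for fidelity comparisons.
#'
#' @param model a \linkS4class{BeadModel}.
#' @param pose a \linkS4class{Pose}.
#' @param stage \code{"surface"} or \code{"center"}.
#' @return The posed \linkS4class{BeadModel}.
#' @export
transformModel <- function(model, pose, stage = c("surface", "center")) {
  stage <- match.arg(stage)
  xyz <- coords(model)
  cen <- colMeans(xyz)
  rot <- sweep(xyz, 2L, cen) %*% t(.rotZXY(pose@psi, pose@phi, pose@theta))
  rot[, 1L] <- rot[, 1L] + pose@x
  rot[, 2L] <- rot[, 2L] + pose@y
  zref <- if (stage == "surface") min(rot[, 3L] - radii(model)) else min(rot[, 3L])
  rot[, 3L] <- rot[, 3L] - zref
  BeadModel(rot, radii(model), kinds(model), name = model@name)
}

#' Tip-apex height at first contact with a bead
#'
#' Vectorized over beads: given bead apex positions and a lateral tip
#' position, returns the tip-apex z at which a descending sphere-capped-cone
#' tip first touches each bead.
#'
#' @param beadZ bead center z (nm), vector.
#' @param beadR bead radius (nm), vector.
#' @param lateralDist lateral distance from the tip axis to the bead center
#'   (nm), vector.
#' @param tip a \linkS4class{TipModel}.
#' @return numeric vector of contact heights (nm; may be negative for beads
#'   below the stage).
#' @export
contactHeight <- function(beadZ, beadR, lateralDist, tip) {
  stopifnot(is(tip, "TipModel"))
  n <- max(length(beadZ), length(beadR), length(lateralDist))
  .cpp_contact_height(rep_len(as.numeric(beadZ), n),
                      rep_len(as.numeric(beadR), n),
                      rep_len(as.numeric(lateralDist), n),
                      tip@radius, tip@halfAngle)
}

#' Render a noise-free pseudo-AFM image
#'
#' @param model a \linkS4class{BeadModel} (one conformer).
#' @param pose a \linkS4class{Pose} applied via \code{\link{transformModel}}.
#' @param tip a \linkS4class{TipModel}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param stage stage-height convention, see \code{\link{transformModel}}.
#' @return A \linkS4class{HeightImage}; all pixel values >= 0.
#' @examples
#' bm <- BeadModel(rbind(c(0, 0, 1)), radii = 1, kinds = "ALA")
#' img <- renderImage(bm, Pose(), TipModel(1, 10), ImageGrid(16, 16, 0.5))
#' max(heights(img))  # sphere of radius 1 resting on the stage: apex at 2 nm
#' @export
renderImage <- function(model, pose = Pose(), tip = TipModel(),
                        grid = ImageGrid(), stage = "surface") {
  vals <- .renderPosedRows(model, pose, tip, grid, seq_len(grid@ny), stage)
  HeightImage(vals, grid)
}

## shared pose+render kernel; `rows` selects scan lines (1 = bottom)
.renderPosedRows <- function(model, pose, tip, grid, rows, stage = "surface") {
  .cpp_render_posed(coords(model), radii(model),
                    pose@x, pose@y, pose@phi, pose@theta, pose@psi,
                    tip@radius, tip@halfAngle, grid@nx, grid@pixelSize,
                    grid@origin[1L], grid@origin[2L], as.integer(rows),
                    identical(stage, "surface"))
}

#' Imaging-parameter sampling grids
#'
#' The discrete grids from which tip and orientation parameters are drawn
#' when a training set is generated: probe radius 1.0-3.0 nm in 0.1 nm
#' steps, half-apex angle 5-30 deg in 1 deg steps, tilts phi and theta
#' -20..20 deg in 1 deg steps (the nanodisc stays near-parallel to the
#' stage), and in-plane rotation psi -180..180 deg in 1 deg steps.
#'
#' @param Rrange,Rstep probe-radius range (nm) and step.
#' @param thetaTipRange,thetaTipStep half-apex angle range (deg) and step.
#' @param tiltRange,tiltStep phi/theta tilt range (deg) and step.
#' @param psiRange,psiStep in-plane rotation range (deg) and step.
#' @param xRange,yRange lateral offset ranges (nm); degenerate 0 by default
#'   (lateral variation is added later as whole-pixel shifts).
#' @return list of numeric grids, one per parameter.
#' @export
simParamRanges <- function(Rrange = c(1.0, 3.0), Rstep = 0.1,
                           thetaTipRange = c(5, 30), thetaTipStep = 1,
                           tiltRange = c(-20, 20), tiltStep = 1,
                           psiRange = c(-180, 180), psiStep = 1,
                           xRange = c(0, 0), yRange = c(0, 0)) {
  gridOf <- function(range, step) {
    if (range[2L] < range[1L]) stop("empty parameter range")
    seq(range[1L], range[2L], by = step)
  }
  list(R = gridOf(Rrange, Rstep),
       thetaTip = gridOf(thetaTipRange, thetaTipStep),
       phi = gridOf(tiltRange, tiltStep),
       theta = gridOf(tiltRange, tiltStep),
       psi = gridOf(psiRange, psiStep),
       x = if (diff(range(xRange)) == 0) xRange[1L] else gridOf(xRange, 0.1),
       y = if (diff(range(yRange)) == 0) yRange[1L] else gridOf(yRange, 0.1))
}

#' Draw a random tip and pose from the parameter grids
#'
#' Uses the R random stream; seed with \code{set.seed} for reproducibility.
#'
#' @param ranges grids from \code{\link{simParamRanges}}.
#' @return list with elements \code{tip} (\linkS4class{TipModel}) and
#'   \code{pose} (\linkS4class{Pose}).
#' @export
sampleSimParams <- function(ranges = simParamRanges()) {
  pick <- function(g) if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
  tip <- TipModel(radius = pick(ranges$R), halfAngle = pick(ranges$thetaTip))
  pose <- Pose(x = pick(ranges$x), y = pick(ranges$y), phi = pick(ranges$phi),
               theta = pick(ranges$theta), psi = pick(ranges$psi))
  list(tip = tip, pose = pose)
}
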