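## Synthetic conformational ensembles.
##
## A two-arm hinge molecule with K planted, evenly spaced hinge angles plays
## the role of an MD ensemble with ordered conformational states: the hinge
## opening mimics a closed-to-wide-open domain motion that is resolvable at
## the working pixel size, and i.i.d. Gaussian bead jitter mimics
## within-state thermal fluctuation. Every downstream stage (clustering,
## dataset generation, training, fitting) is exercised on it without any
## external data.

#' Specification of the hinge fixture
#'
#' Defaults are sized so a 36 x 36 image at 0.8 nm/pixel resolves the motion
#' and a desk-scale training run converges in minutes: K = 4 states, 12
#' beads per arm of 6 nm, bead radius 0.8 nm, hinge angles evenly spaced
#' over 40-120 degrees, within-state jitter 0.15 nm, 250 frames per state.
#'
#' @param K planted state count (>= 2).
#' @param beadsPerArm beads per rigid arm.
#' @param beadRadius bead radius in nm.
#' @param armLength arm length in nm.
#' @param angleRange hinge-angle range (deg), closed to wide-open.
#' @param jitterSigma per-coordinate Gaussian jitter s.d. in nm.
#' @param framesPerState conformers per state.
#' @param seed RNG seed used by \code{\link{makeHingeEnsemble}}.
#' @return a named list (hinge spec).
#' @export
hingeSpec <- function(K = 4L, beadsPerArm = 12L, beadRadius = 0.8,
                      armLength = 6, angleRange = c(40, 120),
                      jitterSigma = 0.15, framesPerState = 250L, seed = 1L) {
  stopifnot(K >= 2L, jitterSigma >= 0, armLength > 0, beadsPerArm >= 2L)
  list(K = as.integer(K), beadsPerArm = as.integer(beadsPerArm),
       beadRadius = beadRadius, armLength = armLength,
       angleRange = angleRange, jitterSigma = jitterSigma,
       framesPerState = as.integer(framesPerState), seed = as.integer(seed))
}

#' Planted hinge angles of a spec
#'
#' State k (1..K) opens the hinge to the k-th value evenly spaced across
#' \code{angleRange}.
#'
#' @param spec a \code{\link{hingeSpec}}.
#' @return numeric vector of K angles in degrees.
#' @export
hingeAngles <- function(spec) {
  seq(spec$angleRange[1L], spec$angleRange[2L], length.out = spec$K)
}

## One hinge conformer: arm A lies on the stage along +x; arm B shares the
## pivot and opens OUT of the stage plane (in the x-z plane) by the hinge
## angle. Opening therefore changes the height profile, the observable an
## AFM actually measures for a closed-to-wide-open domain motion, as well
## as the footprint - so planted states stay resolvable under arbitrary
## in-plane rotation of the molecule.
.hingeConformer <- function(spec, angle) {
  n <- spec$beadsPerArm
  t <- seq_len(n) / n * spec$armLength  # pivot excluded, bead n at arm tip
  armA <- cbind(t, 0, 0)
  a <- angle * pi / 180
  armB <- cbind(t * cos(a), 0, t * sin(a))
  xyz <- rbind(c(0, 0, 0), armA, armB)        # pivot bead + two arms
  xyz[, 3L] <- xyz[, 3L] + spec$beadRadius    # rest the chain on the stage
  xyz
}

#' Generate the hinge-motion ensemble
#'
#' Frames are grouped by state (all frames of state 1, then state 2, ...);
#' each frame adds i.i.d. Gaussian jitter of scale \code{jitterSigma} to all
#' bead coordinates. Fully seeded by \code{spec$seed}.
#'
#' @param spec a \code{\link{hingeSpec}}.
#' @return list with \code{ensemble} (an \linkS4class{Ensemble}) and
#'   \code{labels} (integer planted state per frame, ordered with the hinge
#'   angle).
#' @export
makeHingeEnsemble <- function(spec = hingeSpec()) {
  set.seed(spec$seed)
  angles <- hingeAngles(spec)
  nb <- 2L * spec$beadsPerArm + 1L
  conf <- vector("list", spec$K * spec$framesPerState)
  labels <- integer(length(conf))
  i <- 0L
  for (k in seq_len(spec$K)) {
    base <- .hingeConformer(spec, angles[k])
    for (f in seq_len(spec$framesPerState)) {
      i <- i + 1L
      xyz <- base + matrix(rnorm(3L * nb, 0, spec$jitterSigma), nb, 3L)
      conf[[i]] <- BeadModel(xyz, spec$beadRadius, "HNG",
                             name = sprintf("state%d.%d", k, f))
      labels[i] <- k
    }
  }
  list(ensemble = Ensemble(conf), labels = labels)
}

#' Linear Cartesian morph between two conformers
#'
#' Stand-in for a morphing trajectory: straight-line interpolation of bead
#' coordinates between two endpoint structures, endpoints preserved exactly.
#' Useful for probing classifier behaviour on conformations that fall
#' between (or outside) the sampled states.
#'
#' @param a,b matched \linkS4class{BeadModel}s (same bead count and kinds).
#' @param nSnapshots number of snapshots including both endpoints (>= 2).
#' @return list of \code{nSnapshots} \linkS4class{BeadModel}s.
#' @export
linearMorph <- function(a, b, nSnapshots) {
  stopifnot(nBeads(a) == nBeads(b), all(kinds(a) == kinds(b)), nSnapshots >= 2L)
  lam <- seq(0, 1, length.out = nSnapshots)
  lapply(seq_along(lam), function(i) {
    BeadModel(coords(a) * (1 - lam[i]) + coords(b) * lam[i],
              radii(a), kinds(a), name = sprintf("morph%d", i))
  })
}

#' Reference nanodisc-plus-protein scene
#'
#' A flat ring of PO4-like beads (the nanodisc rim, parallel to the stage)
#' with the hinge protein mounted above its center, mimicking the end-up
#' membrane-protein-on-nanodisc geometry for which small tilt limits
#' (|phi|, |theta| <= 20 deg) are physically meaningful.
#'
#' @param spec a \code{\link{hingeSpec}} for the mounted protein.
#' @param discRadius ring radius in nm.
#' @param discBeads number of beads in the ring.
#' @param po4Radius disc bead radius in nm.
#' @return list with \code{disc} and \code{protein}
#'   (\linkS4class{BeadModel}s) and \code{scene} (their union).
#' @export
makeReferenceScene <- function(spec = hingeSpec(), discRadius = 5,
                               discBeads = 24L, po4Radius = 0.47) {
  ang <- 2 * pi * (seq_len(discBeads) - 1L) / discBeads
  disc <- cbind(discRadius * cos(ang), discRadius * sin(ang), po4Radius)
  discModel <- BeadModel(disc, po4Radius, "PO4", name = "disc")
  prot <- .hingeConformer(spec, mean(spec$angleRange))
  prot[, 1L] <- prot[, 1L] - spec$armLength / 2   # roughly center laterally
  prot[, 3L] <- prot[, 3L] + 2 * po4Radius        # mounted above the disc
  protModel <- BeadModel(prot, spec$beadRadius, "HNG", name = "protein")
  scene <- BeadModel(rbind(disc, prot),
                     c(rep(po4Radius, discBeads), rep(spec$beadRadius, nrow(prot))),
                     c(rep("PO4", discBeads), rep("HNG", nrow(prot))),
                     name = "scene")
  list(disc = discModel, protein = protModel, scene = scene)
}
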