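#' @name accessors
#' @title Accessors for afmstate core classes
#' @description Slot accessors; user code should use these instead of `@`.
#' @param object an afmstate S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "BeadModel", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))
#' @rdname accessors
#' @export
setMethod("radii", "BeadModel", function(object) object@radii)

#' @rdname accessors
#' @export
setGeneric("kinds", function(object) standardGeneric("kinds"))
#' @rdname accessors
#' @export
setMethod("kinds", "BeadModel", function(object) object@kinds)

#' @rdname accessors
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setMethod("nBeads", "BeadModel", function(object) nrow(object@coords))

#' @rdname accessors
#' @export
setGeneric("nConformers", function(object) standardGeneric("nConformers"))
#' @rdname accessors
#' @export
setMethod("nConformers", "Ensemble", function(object) length(object@conformers))

#' @rdname accessors
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))
#' @rdname accessors
#' @export
setMethod("conformers", "Ensemble", function(object) object@conformers)

#' @rdname accessors
#' @export
setGeneric("frameIds", function(object) standardGeneric("frameIds"))
#' @rdname accessors
#' @export
setMethod("frameIds", "Ensemble", function(object) object@frameIds)

#' Extract a conformer from an ensemble
#' @param x an \linkS4class{Ensemble}.
#' @param i conformer index.
#' @param j,drop,... ignored.
#' @export
setMethod("[[", "Ensemble", function(x, i, j, ...) x@conformers[[i]])

#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))
#' @rdname accessors
#' @export
setMethod("heights", "HeightImage", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("imageGrid", function(object) standardGeneric("imageGrid"))
#' @rdname accessors
#' @export
setMethod("imageGrid", "HeightImage", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "StateModel", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("stateCenters", function(object) standardGeneric("stateCenters"))
#' @rdname accessors
#' @export
setMethod("stateCenters", "StateModel", function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setMethod("nStates", "StateModel", function(object) object@K)

#' @rdname accessors
#' @export
setGeneric("projections", function(object) standardGeneric("projections"))
#' @rdname accessors
#' @export
setMethod("projections", "StateModel", function(object) object@projections)

#' @rdname accessors
#' @export
setGeneric("bicTable", function(object) standardGeneric("bicTable"))
#' @rdname accessors
#' @export
setMethod("bicTable", "StateModel", function(object) object@bicTable)

#' Pose as a named numeric vector
#' @param pose a \linkS4class{Pose}.
#' @return named numeric (x, y, phi, theta, psi).
#' @export
poseVector <- function(pose) {
  c(x = pose@x, y = pose@y, phi = pose@phi, theta = pose@theta, psi = pose@psi)
}

setMethod("show", "BeadModel", function(object) {
  cat(sprintf("BeadModel '%s': %d beads, radius range [%.3g, %.3g] nm\n",
              object@name, nBeads(object), min(object@radii), max(object@radii)))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d conformers x %d beads\n",
              nConformers(object), nBeads(object@conformers[[1L]])))
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf("TipModel: R = %.3g nm, Theta = %.3g deg\n",
              object@radius, object@halfAngle))
})

setMethod("show", "Pose", function(object) {
  v <- poseVector(object)
  cat(sprintf("Pose: x=%.3g y=%.3g nm; phi=%.3g theta=%.3g psi=%.3g deg\n",
              v[1], v[2], v[3], v[4], v[5]))
})

setMethod("show", "HeightImage", function(object) {
  g <- object@grid
  cat(sprintf("HeightImage: %d x %d px @ %.3g nm/px, heights [%.3g, %.3g] nm\n",
              g@nx, g@ny, g@pixelSize, min(object@values), max(object@values)))
})

setMethod("show", "StateModel", function(object) {
  if (length(object@K) && object@K > 0L) {
    occ <- tabulate(object@labels, object@K)
    cat(sprintf("StateModel: K = %d states over %d frames (occupancy %s)\n",
                object@K, length(object@labels),
                paste(occ, collapse = "/")))
  } else {
    cat(sprintf("StateModel (PCA only): %d components over %d frames\n",
                object@nPC, nrow(object@projections)))
  }
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: state %d, cc = %.4f, shift (%d, %d) px\n",
    object@state, object@cc, object@shift[1], object@shift[2]))
  show(object@pose)
  show(object@tip)
})
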