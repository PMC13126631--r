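#' @import methods
#' @importFrom stats prcomp rnorm runif sd dist mahalanobis quantile median mad
#' @importFrom utils tar untar head tail
#' @useDynLib afmstate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## All lengths are nanometres and all angles degrees unless a slot name says
## otherwise. Image arrays are ny x nx matrices; row i maps to the i-th scan
## line counted from the bottom (+y), column j to the fast (x) axis.

#' Coarse-grained bead model of one conformer
#'
#' A molecule represented as spheres: one bead per amino-acid residue (placed
#' at the C-alpha position) or per lipid phosphate group. This is the
#' collision geometry scanned by the simulated AFM tip.
#'
#' @slot coords numeric matrix (n x 3), bead centers in nm.
#' @slot radii numeric vector, effective bead radii in nm (all > 0).
#' @slot kinds character vector, residue code per bead (e.g. "ALA", "PO4").
#' @slot name single character label.
#' @export
setClass("BeadModel", representation(
  coords = "matrix", radii = "numeric", kinds = "character", name = "character"
))

setValidity("BeadModel", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("BeadModel must contain at least one bead")
  if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
  if (!all(is.finite(object@coords))) return("bead centers must be finite")
  if (length(object@radii) != n || length(object@kinds) != n)
    return("radii and kinds must match the number of beads")
  if (!all(is.finite(object@radii)) || any(object@radii <= 0))
    return("bead radii must be positive and finite")
  TRUE
})

#' Conformational ensemble
#'
#' An ordered collection of conformers of one molecule. All conformers must
#' have identical bead counts and kinds so that bead i corresponds to the
#' same residue in every frame.
#'
#' @slot conformers list of \linkS4class{BeadModel}.
#' @slot frameIds integer vector of frame identifiers.
#' @export
setClass("Ensemble", representation(conformers = "list", frameIds = "integer"))

setValidity("Ensemble", function(object) {
  if (length(object@conformers) == 0L) return("Ensemble must be non-empty")
  if (length(object@frameIds) != length(object@conformers))
    return("frameIds must match the number of conformers")
  if (!all(vapply(object@conformers, is, logical(1), "BeadModel")))
    return("conformers must all be BeadModel objects")
  k0 <- object@conformers[[1L]]@kinds
  for (cm in object@conformers) {
    if (length(cm@kinds) != length(k0) || !all(cm@kinds == k0))
      return("all conformers must share identical bead counts and kinds")
  }
  TRUE
})

#' AFM tip geometry: cone capped by a sphere
#'
#' @slot radius probe sphere radius R in nm (> 0).
#' @slot halfAngle cone half-apex angle Theta in degrees (0, 90).
#' @export
setClass("TipModel", representation(radius = "numeric", halfAngle = "numeric"))

setValidity("TipModel", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    return("tip radius must be a single positive number")
  if (length(object@halfAngle) != 1L || !is.finite(object@halfAngle) ||
      object@halfAngle <= 0 || object@halfAngle >= 90)
    return("halfAngle must lie strictly between 0 and 90 degrees")
  TRUE
})

#' Molecular pose on the stage
#'
#' Lateral offset plus three rotation angles. Rotations are applied about the
#' model centroid sequentially about the fixed z-, x- and y-axes (psi, phi,
#' theta) before the lateral translation and the stage height convention.
#'
#' @slot x,y lateral offsets in nm.
#' @slot phi,theta tilts about the x- and y-axes in degrees.
#' @slot psi rotation about the z-axis in degrees.
#' @export
setClass("Pose", representation(
  x = "numeric", y = "numeric", phi = "numeric", theta = "numeric", psi = "numeric"
))

setValidity("Pose", function(object) {
  v <- c(object@x, object@y, object@phi, object@theta, object@psi)
  if (length(v) != 5L || !all(is.finite(v))) return("pose components must be finite scalars")
  TRUE
})

#' Pixel grid of a height image
#'
#' Pixel (i, j) (row i from the bottom, column j from the left, 1-based) has
#' its center at \code{origin + (j - 0.5, i - 0.5) * pixelSize}.
#'
#' @slot nx,ny pixel counts (>= 1).
#' @slot pixelSize pixel edge in nm (> 0).
#' @slot origin nm position of the lower-left image corner, length 2.
#' @export
setClass("ImageGrid", representation(
  nx = "integer", ny = "integer", pixelSize = "numeric", origin = "numeric"
))

setValidity("ImageGrid", function(object) {
  if (object@nx < 1L || object@ny < 1L) return("nx and ny must be >= 1")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be positive")
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    return("origin must be a finite length-2 vector")
  TRUE
})

#' Height map in nanometres
#'
#' @slot values ny x nx numeric matrix of heights in nm.
#' @slot grid an \linkS4class{ImageGrid}.
#' @export
setClass("HeightImage", representation(values = "matrix", grid = "ImageGrid"))

setValidity("HeightImage", function(object) {
  g <- object@grid
  if (nrow(object@values) != g@ny || ncol(object@values) != g@nx)
    return("values must be a ny x nx matrix matching the grid")
  if (!all(is.finite(object@values))) return("heights must be finite")
  TRUE
})

#' Line-scan lag noise parameters
#'
#' Per scan line the lateral position and orientation of the molecule are
#' displaced from their t = 0 values by zero-mean Gaussian perturbations of
#' variance \code{s * var_i}, truncated by rejection so that
#' \code{sqrt(dx^2 + dy^2) <= w * drMax} and each angle stays within
#' \code{w} times its own bound. The defaults are the reference noise set
#' used throughout: var x = var y = 0.81 nm^2, var phi = var theta =
#' 6.25 deg^2, var psi = 25 deg^2, drMax = 1.2 nm, dphiMax = dthetaMax = 5
#' deg, dpsiMax = 10 deg, s = w = 1.
#'
#' @slot s variance scaling factor (dimensionless, >= 0).
#' @slot w truncation scaling factor (dimensionless, >= 0).
#' @slot varX,varY lateral variances in nm^2.
#' @slot varPhi,varTheta,varPsi angular variances in deg^2.
#' @slot drMax lateral truncation radius in nm.
#' @slot dphiMax,dthetaMax,dpsiMax angular truncation bounds in deg.
#' @export
setClass("ScanNoiseParams", representation(
  s = "numeric", w = "numeric",
  varX = "numeric", varY = "numeric",
  varPhi = "numeric", varTheta = "numeric", varPsi = "numeric",
  drMax = "numeric", dphiMax = "numeric", dthetaMax = "numeric", dpsiMax = "numeric"
))

setValidity("ScanNoiseParams", function(object) {
  v <- c(object@s, object@w, object@varX, object@varY, object@varPhi,
         object@varTheta, object@varPsi, object@drMax, object@dphiMax,
         object@dthetaMax, object@dpsiMax)
  if (!all(is.finite(v)) || any(v < 0))
    return("all scan-noise parameters must be finite and >= 0")
  TRUE
})

#' Ordered conformational state model
#'
#' PCA basis plus Gaussian-mixture cluster assignment of an ensemble.
#' State labels 1..K are ordered so the per-state mean of the first principal
#' component is non-decreasing, i.e. labels follow the conformational
#' transition. Each state's center is the member conformer nearest to the
#' cluster mean in the retained PC subspace.
#'
#' @slot pcaMean flat coordinate mean vector (3n) of the superposed ensemble.
#' @slot pcaComponents matrix (3n x nPC) of principal axes (orthonormal columns).
#' @slot sdev per-component standard deviations of all computed PCs.
#' @slot nPC number of components retained for clustering.
#' @slot projections matrix (frames x nPC) of scores used for clustering.
#' @slot labels integer state index per conformer (1..K), PC1-ordered.
#' @slot centers integer conformer index per state (nearest to cluster mean).
#' @slot K number of states.
#' @slot orderKey per-state mean PC1 (non-decreasing).
#' @slot bicTable BIC value per candidate cluster count (named numeric).
#' @export
setClass("StateModel", representation(
  pcaMean = "numeric", pcaComponents = "matrix", sdev = "numeric",
  nPC = "integer", projections = "matrix",
  labels = "integer", centers = "integer", K = "integer",
  orderKey = "numeric", bicTable = "numeric"
))

setValidity("StateModel", function(object) {
  if (length(object@K) && object@K > 0L) {
    if (any(object@labels < 1L) || any(object@labels > object@K))
      return("labels must lie in 1..K")
    if (length(object@centers) != object@K)
      return("one center per state is required")
    if (is.unsorted(object@orderKey))
      return("states must be ordered by non-decreasing mean PC1")
    for (k in seq_len(object@K)) {
      if (object@labels[object@centers[k]] != k)
        return("each center must be a member of its own cluster")
    }
  }
  TRUE
})

#' Result of exhaustive-grid rigid-body fitting
#'
#' @slot state index of the best-fitting candidate structure.
#' @slot pose best \linkS4class{Pose}.
#' @slot tip best \linkS4class{TipModel}.
#' @slot shift integer pixel shift (dx, dy) applied to the rendered image.
#' @slot cc maximum pixel correlation coefficient over the searched grid.
#' @slot table data.frame of the top-scoring grid points.
#' @export
setClass("FitResult", representation(
  state = "integer", pose = "Pose", tip = "TipModel",
  shift = "integer", cc = "numeric", table = "data.frame"
))
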