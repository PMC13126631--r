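#' Construct a BeadModel
#'
#' @param coords n x 3 numeric matrix of bead centers (nm).
#' @param radii numeric vector of bead radii (nm), recycled if length 1.
#' @param kinds character vector of bead kinds, recycled if length 1.
#' @param name label for the model.
#' @return A \linkS4class{BeadModel}.
#' @examples
#' bm <- BeadModel(rbind(c(0, 0, 1), c(0, 0, 3)), radii = 1, kinds = "ALA")
#' nBeads(bm)
#' @export
BeadModel <- function(coords, radii, kinds = "BEAD", name = "model") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  new("BeadModel", coords = coords, radii = rep_len(as.numeric(radii), n),
      kinds = rep_len(as.character(kinds), n), name = as.character(name)[1L])
}

#' Construct an Ensemble
#'
#' @param conformers list of \linkS4class{BeadModel} with identical bead
#'   counts and kinds.
#' @param frameIds optional integer frame identifiers (default 1..n).
#' @return An \linkS4class{Ensemble}.
#' @export
Ensemble <- function(conformers, frameIds = seq_along(conformers)) {
  new("Ensemble", conformers = conformers, frameIds = as.integer(frameIds))
}

#' Construct a TipModel
#'
#' @param radius probe sphere radius R in nm.
#' @param halfAngle cone half-apex angle Theta in degrees.
#' @return A \linkS4class{TipModel}.
#' @examples
#' tip <- TipModel(radius = 1, halfAngle = 10)
#' @export
TipModel <- function(radius = 1, halfAngle = 10) {
  new("TipModel", radius = as.numeric(radius), halfAngle = as.numeric(halfAngle))
}

#' Construct a Pose
#'
#' @param x,y lateral offsets in nm.
#' @param phi,theta tilts about the x- and y-axes in degrees.
#' @param psi rotation about the z-axis in degrees.
#' @return A \linkS4class{Pose}.
#' @examples
#' Pose(psi = 90)
#' @export
Pose <- function(x = 0, y = 0, phi = 0, theta = 0, psi = 0) {
  new("Pose", x = as.numeric(x), y = as.numeric(y), phi = as.numeric(phi),
      theta = as.numeric(theta), psi = as.numeric(psi))
}

#' Construct an ImageGrid
#'
#' @param nx,ny pixel counts. The defaults (36 x 36 at 0.8 nm/pixel) match
#'   typical HS-AFM working resolution.
#' @param pixelSize pixel edge in nm.
#' @param origin nm position of the lower-left corner; by default the grid is
#'   centered on (0, 0).
#' @return An \linkS4class{ImageGrid}.
#' @export
ImageGrid <- function(nx = 36L, ny = 36L, pixelSize = 0.8, origin = NULL) {
  if (is.null(origin))
    origin <- c(-nx * pixelSize / 2, -ny * pixelSize / 2)
  new("ImageGrid", nx = as.integer(nx), ny = as.integer(ny),
      pixelSize = as.numeric(pixelSize), origin = as.numeric(origin))
}

#' Construct a HeightImage
#'
#' @param values ny x nx matrix of heights in nm.
#' @param grid an \linkS4class{ImageGrid}; defaults to a grid matching
#'   \code{dim(values)} at 0.8 nm/pixel.
#' @return A \linkS4class{HeightImage}.
#' @export
HeightImage <- function(values, grid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- ImageGrid(nx = ncol(values), ny = nrow(values))
  new("HeightImage", values = values, grid = grid)
}

#' Construct scan-lag noise parameters
#'
#' Defaults are the reference noise set (see the class description).
#'
#' @param s,w variance and truncation scaling factors (dimensionless).
#' @param varX,varY lateral variances (nm^2).
#' @param varPhi,varTheta,varPsi angular variances (deg^2).
#' @param drMax lateral truncation radius (nm).
#' @param dphiMax,dthetaMax,dpsiMax angular truncation bounds (deg).
#' @return A \linkS4class{ScanNoiseParams}.
#' @examples
#' ScanNoiseParams()          # reference set
#' ScanNoiseParams(s = 0)     # degenerate: no perturbation
#' @export
ScanNoiseParams <- function(s = 1, w = 1, varX = 0.81, varY = 0.81,
                            varPhi = 6.25, varTheta = 6.25, varPsi = 25,
                            drMax = 1.2, dphiMax = 5, dthetaMax = 5,
                            dpsiMax = 10) {
  new("ScanNoiseParams", s = as.numeric(s), w = as.numeric(w),
      varX = as.numeric(varX), varY = as.numeric(varY),
      varPhi = as.numeric(varPhi), varTheta = as.numeric(varTheta),
      varPsi = as.numeric(varPsi), drMax = as.numeric(drMax),
      dphiMax = as.numeric(dphiMax), dthetaMax = as.numeric(dthetaMax),
      dpsiMax = as.numeric(dpsiMax))
}
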