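## Conformational state definition.
##
## States are defined in two steps: (1) PCA on the superposed, flattened
## bead coordinates of the ensemble; (2) Gaussian-mixture clustering of the
## first nPC principal-component scores, with the cluster count chosen by
## BIC subject to a minimum per-cluster occupancy. Labels are then reordered
## so state 1..K follows the transition (non-decreasing mean PC1), and each
## state is represented by the member nearest to its cluster mean.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation that superpose model \code{b} onto
#' model \code{a} with minimum RMSD.
#'
#' @param a,b \linkS4class{BeadModel}s with equal bead counts.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd} (nm), and \code{transformed} (the superposed copy of b).
#' @export
superpose <- function(a, b) {
  A <- coords(a); B <- coords(b)
  if (nrow(A) != nrow(B)) stop("bead counts differ")
  if (nrow(A) < 3L || qr(sweep(A, 2L, colMeans(A)))$rank < 2L)
    stop("degenerate geometry: need >= 3 non-collinear beads")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  trans <- ca - as.numeric(R %*% cb)
  BT <- sweep(fitted, 2L, ca, `+`)
  list(rotation = R, translation = trans, rmsd = rmsd,
       transformed = BeadModel(BT, radii(b), kinds(b), name = b@name))
}

.flattenAligned <- function(ens, reference = 1L) {
  ref <- ens[[reference]]
  t(vapply(seq_len(nConformers(ens)), function(i) {
    as.numeric(t(coords(superpose(ref, ens[[i]])$transformed)))
  }, numeric(3L * nBeads(ref))))
}

#' PCA of an ensemble
#'
#' Conformers are rigid-body superposed onto the first frame (removing
#' translation/rotation from the state definition), flattened to 3n-vectors
#' and decomposed by PCA. Returns a partial \linkS4class{StateModel}
#' (labels and centers unset) carrying the basis and projections that
#' \code{\link{clusterGMM}} consumes.
#'
#' @param ens an \linkS4class{Ensemble} with more than \code{nPC} conformers.
#' @param nPC number of principal components to retain (default 6).
#' @param align superpose conformers onto the first frame first (default).
#' @return A \linkS4class{StateModel} with \code{K = 0}.
#' @export
fitPCA <- function(ens, nPC = 6L, align = TRUE) {
  n <- nConformers(ens)
  if (n < nPC + 1L) stop("need at least nPC + 1 conformers")
  X <- if (align) .flattenAligned(ens) else
    t(vapply(seq_len(n), function(i) as.numeric(t(coords(ens[[i]]))),
             numeric(3L * nBeads(ens[[1L]]))))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < nPC) {
    warning("rank-deficient ensemble: retaining ", rank,
            " components instead of ", nPC)
    nPC <- rank
  }
  new("StateModel",
      pcaMean = as.numeric(pc$center),
      pcaComponents = pc$rotation[, seq_len(nPC), drop = FALSE],
      sdev = pc$sdev, nPC = as.integer(nPC),
      projections = pc$x[, seq_len(nPC), drop = FALSE],
      labels = integer(0), centers = integer(0), K = 0L,
      orderKey = numeric(0), bicTable = numeric(0))
}

#' @importFrom mclust Mclust mclustBIC
NULL

#' Gaussian-mixture clustering of PCA projections
#'
#' Fits full-covariance Gaussian mixtures for every candidate cluster count,
#' selects the BIC-optimal count among those where every cluster holds at
#' least \code{minOccupancy} members, relabels states in increasing order of
#' mean PC1, and records each state's representative conformer (the member
#' nearest to the cluster mean in the retained PC subspace).
#'
#' @param sm a partial \linkS4class{StateModel} from \code{\link{fitPCA}}.
#' @param kRange candidate cluster counts.
#' @param minOccupancy minimum members per cluster; default 1\% of frames.
#' @param seed seed for the mixture fit (kept explicit for reproducibility;
#'   initialization is deterministic model-based hierarchical clustering).
#' @return the completed \linkS4class{StateModel}.
#' @export
clusterGMM <- function(sm, kRange = 2:30, minOccupancy = NULL, seed = 1L) {
  proj <- sm@projections
  n <- nrow(proj)
  if (n <= max(kRange)) stop("need more frames than the largest candidate K")
  if (is.null(minOccupancy)) minOccupancy <- max(1L, floor(0.01 * n))
  set.seed(seed)
  bic <- setNames(rep(NA_real_, length(kRange)), kRange)
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    fit <- tryCatch(
      mclust::Mclust(proj, G = kRange[i], modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    occ <- tabulate(fit$classification, kRange[i])
    fits[[i]] <- fit
    bic[i] <- fit$bic  # mclust convention: larger is better
    if (min(occ) < minOccupancy) bic[i] <- -Inf  # inadmissible
  }
  if (all(!is.finite(bic))) {
    stop("no admissible cluster count; BIC table: ",
         paste(sprintf("K=%s:%.1f", names(bic), bic), collapse = ", "))
  }
  best <- which.max(bic)
  fit <- fits[[best]]
  K <- kRange[best]
  raw <- fit$classification

  ## PC1-ordering: permute labels so mean PC1 is non-decreasing in the label
  meanPC1 <- vapply(seq_len(K), function(k) mean(proj[raw == k, 1L]), numeric(1))
  ord <- order(meanPC1)
  relab <- integer(K); relab[ord] <- seq_len(K)
  labels <- relab[raw]

  centers <- integer(K)
  for (k in seq_len(K)) {
    members <- which(labels == k)
    mu <- colMeans(proj[members, , drop = FALSE])
    d2 <- rowSums(sweep(proj[members, , drop = FALSE], 2L, mu)^2)
    centers[k] <- members[which.min(d2)]
  }
  keepBic <- bic
  new("StateModel",
      pcaMean = sm@pcaMean, pcaComponents = sm@pcaComponents, sdev = sm@sdev,
      nPC = sm@nPC, projections = proj,
      labels = as.integer(labels), centers = centers, K = as.integer(K),
      orderKey = sort(meanPC1), bicTable = keepBic)
}

#' Within- and between-state RMSD statistics
#'
#' Within each state: the mean pairwise superposed RMSD over its members
#' (all pairs up to \code{maxMembers} members, else a deterministic
#' evenly spaced subsample of that size). Between: the superposed RMSD of
#' the center conformers of adjacent states (k, k+1).
#'
#' @param ens the \linkS4class{Ensemble} the model was fitted on.
#' @param sm a completed \linkS4class{StateModel}.
#' @param maxMembers per-state member cap for the pairwise computation.
#' @return list with \code{within} (length K) and \code{between}
#'   (length K - 1), both in nm.
#' @export
stateRmsdStats <- function(ens, sm, maxMembers = 200L) {
  stopifnot(sm@K > 0L)
  within <- numeric(sm@K)
  for (k in seq_len(sm@K)) {
    members <- which(sm@labels == k)
    if (length(members) > maxMembers)
      members <- members[unique(round(seq(1L, length(members),
                                          length.out = maxMembers)))]
    m <- length(members)
    if (m < 2L) { within[k] <- 0; next }
    tot <- 0; np <- 0L
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      tot <- tot + superpose(ens[[members[i]]], ens[[members[j]]])$rmsd
      np <- np + 1L
    }
    within[k] <- tot / np
  }
  between <- vapply(seq_len(sm@K - 1L), function(k) {
    superpose(ens[[sm@centers[k]]], ens[[sm@centers[k + 1L]]])$rmsd
  }, numeric(1))
  list(within = within, between = between)
}

#' Persist a state model to a directory
#'
#' Writes JSON metadata plus CSV arrays (basis, mean, projections, labels),
#' and, when the ensemble is supplied, the K center conformers both as a
#' multi-model PDB (coordinates back-converted to Angstrom) and in the
#' bead-list text format.
#'
#' @param sm a completed \linkS4class{StateModel}.
#' @param dir output directory (created if needed).
#' @param ens optional source \linkS4class{Ensemble} for center export.
#' @return \code{dir}, invisibly.
#' @export
saveStateModel <- function(sm, dir, ens = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(K = sm@K, nPC = sm@nPC, centers = sm@centers,
               orderKey = sm@orderKey, bicTable = as.list(sm@bicTable),
               sdev = sm@sdev)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  wcsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wcsv(sm@labels, "labels.csv")
  wcsv(sm@pcaMean, "pca_mean.csv")
  wcsv(sm@pcaComponents, "pca_components.csv")
  wcsv(sm@projections, "projections.csv")
  if (!is.null(ens)) {
    centers <- lapply(sm@centers, function(i) ens[[i]])
    writeBeadText(Ensemble(centers), file.path(dir, "centers.txt"))
    xyz <- do.call(rbind, lapply(centers, function(cm)
      as.numeric(t(coords(cm))) * 10))  # nm -> Angstrom
    nb <- nBeads(centers[[1L]])
    bio3d::write.pdb(file = file.path(dir, "centers.pdb"),
                     xyz = bio3d::as.xyz(xyz), resno = seq_len(nb),
                     resid = kinds(centers[[1L]]), elety = rep("CA", nb))
  }
  invisible(dir)
}

#' Load a state model saved by \code{\link{saveStateModel}}
#'
#' @param dir directory path.
#' @return A \linkS4class{StateModel}.
#' @export
loadStateModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rcsv <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  proj <- rcsv("projections.csv")
  dimnames(proj) <- NULL
  comp <- rcsv("pca_components.csv")
  dimnames(comp) <- NULL
  labels <- as.integer(rcsv("labels.csv")[, 1L])
  # -Inf marks inadmissible cluster counts and round-trips via JSON as text
  bt <- vapply(meta$bicTable, function(x) suppressWarnings(as.numeric(x)),
               numeric(1))
  new("StateModel",
      pcaMean = as.numeric(rcsv("pca_mean.csv")[, 1L]),
      pcaComponents = comp, sdev = as.numeric(meta$sdev),
      nPC = as.integer(meta$nPC), projections = proj,
      labels = labels, centers = as.integer(meta$centers),
      K = as.integer(meta$K), orderKey = as.numeric(meta$orderKey),
      bicTable = if (is.null(bt)) numeric(0) else bt)
}
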