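## Coarse-grained model construction.
##
## A protein residue becomes a single sphere at its C-alpha position; a
## nanodisc lipid becomes one sphere per phosphorus atom (the headgroup
## phosphate, "PO4"), with buried acyl chains ignored. PDB coordinates are
## Angstrom and are converted to nm (x 0.1) on load.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "MSE")

.LIPIDS <- c("POPC", "POPE", "POPG", "POPS", "POPA", "DPPC", "DOPC", "DMPC",
             "DLPC", "DLPE", "DOPE", "DOPS", "PLPC")

#' Default per-residue effective bead radius table
#'
#' The effective radius of a one-bead-per-residue representation is not
#' standardized; the conventional C-alpha bead value of 0.38 nm is used for
#' every amino acid unless overridden. Supply your own named vector (3-letter
#' residue codes, nm) to \code{\link{readPDBEnsemble}} for residue-specific
#' radii.
#'
#' @return named numeric vector of radii in nm.
#' @export
defaultRadiusTable <- function() {
  r <- rep(0.38, length(.AA3))
  names(r) <- .AA3
  r
}

#' Read a (multi-model) PDB file as a bead-model ensemble
#'
#' Each protein residue contributes one bead at its C-alpha position with the
#' residue's effective radius; each recognized lipid contributes one bead per
#' phosphorus atom with the PO4 radius. Every MODEL record yields one
#' conformer. Residues lacking a C-alpha atom are skipped with a warning, as
#' are unrecognized HETATM residues.
#'
#' @param path PDB file path.
#' @param radiusTable named numeric vector of per-residue radii in nm;
#'   residues absent from the table fall back to \code{defaultRadius}.
#' @param defaultRadius fallback amino-acid bead radius in nm.
#' @param po4Radius lipid phosphate bead radius in nm (default 0.235 nm, half
#'   the 0.47 nm diameter of a standard coarse-grained phosphate bead).
#' @return An \linkS4class{Ensemble} with coordinates in nm.
#' @export
readPDBEnsemble <- function(path, radiusTable = defaultRadiusTable(),
                            defaultRadius = 0.38, po4Radius = 0.235) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resKey <- paste(at$chain, at$resno, at$insert, at$resid, sep = "|")
  keyOrder <- unique(resKey)

  beadIdx <- integer(0)
  beadKind <- character(0)
  beadRad <- numeric(0)
  skippedNoCA <- character(0)
  skippedOther <- character(0)
  for (key in keyOrder) {
    rows <- which(resKey == key)
    resid <- at$resid[rows[1L]]
    if (resid %in% .AA3) {
      ca <- rows[at$elety[rows] == "CA"]
      if (length(ca) == 0L) { skippedNoCA <- c(skippedNoCA, key); next }
      beadIdx <- c(beadIdx, ca[1L])
      beadKind <- c(beadKind, resid)
      r <- radiusTable[resid]
      beadRad <- c(beadRad, if (is.na(r)) defaultRadius else unname(r))
    } else if (resid %in% .LIPIDS) {
      p <- rows[at$elety[rows] %in% c("P", "PO4", "P1")]
      for (pi in p) {
        beadIdx <- c(beadIdx, pi)
        beadKind <- c(beadKind, "PO4")
        beadRad <- c(beadRad, po4Radius)
      }
    } else {
      skippedOther <- c(skippedOther, resid)
    }
  }
  if (length(skippedNoCA))
    warning(length(skippedNoCA), " residue(s) without a C-alpha atom skipped: ",
            paste(utils::head(skippedNoCA, 5L), collapse = ", "))
  if (length(skippedOther))
    warning("unrecognized residue kind(s) skipped: ",
            paste(unique(skippedOther), collapse = ", "))
  if (length(beadIdx) == 0L) stop("no usable beads found in ", path)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * beadIdx - 2L, 3L * beadIdx - 1L, 3L * beadIdx))
  sub <- xyz[, cols, drop = FALSE]
  if (anyNA(sub))
    stop("inconsistent atom records across MODEL entries in ", path)
  name <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  conf <- lapply(seq_len(nrow(sub)), function(m) {
    cm <- matrix(sub[m, ], ncol = 3L, byrow = TRUE) * 0.1  # Angstrom -> nm
    BeadModel(cm, beadRad, beadKind, name = sprintf("%s#%d", name, m))
  })
  Ensemble(conf)
}

#' Read a bead-list text ensemble
#'
#' Plain-text format: one bead per line, whitespace-separated
#' \code{x y z r kind} (nm); conformers separated by blank lines. The format
#' round-trips with \code{\link{writeBeadText}} at full double precision.
#'
#' @param path file path.
#' @return An \linkS4class{Ensemble}.
#' @export
readBeadText <- function(path) {
  lines <- readLines(path)
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(blank)  # any run of blank lines separates two frames
  keep <- !blank
  if (!any(keep)) stop("no bead lines found in ", path)
  frames <- split(lines[keep], grp[keep])
  conf <- lapply(seq_along(frames), function(i) {
    fl <- frames[[i]]
    parts <- strsplit(trimws(fl), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 5L)
    if (length(bad))
      stop("malformed bead line (expected 'x y z r kind') at frame ", i,
           " line ", bad[1L])
    num <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[1:4]))
      if (anyNA(v)) stop("non-numeric field in bead line: ",
                         paste(p, collapse = " "))
      v
    }, numeric(4)))
    BeadModel(num[, 1:3, drop = FALSE], num[, 4],
              vapply(parts, `[`, character(1), 5L),
              name = sprintf("frame%d", i))
  })
  Ensemble(conf)
}

#' Write an ensemble in the bead-list text format
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBeadText <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nConformers(ens))) {
    cm <- ens[[m]]
    xyz <- coords(cm)
    lines <- sprintf("%s %s %s %s %s",
                     formatC(xyz[, 1], format = "g", digits = 17),
                     formatC(xyz[, 2], format = "g", digits = 17),
                     formatC(xyz[, 3], format = "g", digits = 17),
                     formatC(radii(cm), format = "g", digits = 17),
                     kinds(cm))
    writeLines(lines, con)
    if (m < nConformers(ens)) writeLines("", con)
  }
  invisible(path)
}
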