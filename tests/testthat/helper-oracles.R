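# Shared fixtures and independent oracles used across the suite.

# Brute-force contact-height oracle: discretize the tip profile (surface of
# revolution; h(u) = height above the apex at radial offset u) and lower the
# tip until some surface point touches the bead sphere. The touching apex
# height for profile point (u, h) is zBead + sqrt(r^2 - (u - d)^2) - h, and
# first contact is its maximum over the profile. Independent of the analytic
# two-branch formula.
oracleContactHeight <- function(zBead, rBead, d, R, thetaDeg, du = 2e-4) {
  th <- thetaDeg * pi / 180
  u0 <- R * cos(th)
  umax <- d + rBead + R + 1
  u <- seq(0, umax, by = du)
  h <- ifelse(u <= u0, R - sqrt(pmax(R^2 - u^2, 0)),
              (R - R * sin(th)) + (u - u0) / tan(th))
  # by symmetry the touching tip point lies in the axis/bead plane
  touch <- which(abs(u - d) <= rBead)
  max(zBead + sqrt(rBead^2 - (u[touch] - d)^2) - h[touch])
}

# Simple two-bead model used throughout
twoBeadModel <- function() {
  BeadModel(rbind(c(-1, 0, 1), c(1.5, 0.5, 1.8)),
            radii = c(0.8, 1.0), kinds = c("ALA", "GLY"))
}

# A small hinge fixture shared by state-space and fit tests (cached per run)
smallHinge <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeHingeEnsemble(hingeSpec(framesPerState = 60L, seed = 11L))
    cache
  }
})

# The default-size fixture plus its fitted state model: large enough that
# BIC supports the planted K = 4 (cached per run)
defaultHinge <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- makeHingeEnsemble(hingeSpec())
      sm <- clusterGMM(fitPCA(fx$ensemble), kRange = 2:8, seed = 3)
      cache <<- list(fx = fx, sm = sm)
    }
    cache
  }
})

tinyModelConfig <- function(nStates = 3L) {
  modelConfig(nStates = nStates, imagePx = 12L, patchPx = 6L,
              encLayers = 2L, encDim = 8L, decLayers = 1L, decDim = 4L,
              clsLayers = 1L, heads = 2L, mlpRatio = 2L)
}

# Write a small multi-model PDB with a protein chain and one POPC lipid
writeTestPDB <- function(path, nModels = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  atomLine <- function(serial, name, resname, chain, resno, x, y, z,
                       record = "ATOM") {
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            record, serial, name, resname, chain, resno, x, y, z)
  }
  for (m in seq_len(nModels)) {
    if (nModels > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    off <- (m - 1) * 0.5  # distinct conformers
    writeLines(c(
      atomLine(1, "N", "ALA", "A", 1, 0, 0, 0),
      atomLine(2, "CA", "ALA", "A", 1, 0, 0, 0 + off),
      atomLine(3, "C", "ALA", "A", 1, 1, 0, 0),
      atomLine(4, "CA", "GLY", "A", 2, 0, 0, 5 + off),
      atomLine(5, "CA", "VAL", "A", 3, 3, 1, 2 + off),
      atomLine(6, "P", "POPC", "L", 10, 8, 8, 1, record = "HETATM"),
      atomLine(7, "C1", "POPC", "L", 10, 8.5, 8, 2, record = "HETATM"),
      atomLine(8, "C2", "POPC", "L", 10, 9.0, 8, 3, record = "HETATM")
    ), con)
    if (nModels > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}
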