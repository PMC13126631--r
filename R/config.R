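## Configuration, seeding and provenance.
##
## All randomness descends from one user-visible seed. Module-level work
## (shard generation, stream shuffling, weight init, ...) derives
## independent substreams from (seed, label) with a fixed string hash, so
## adding parallel workers or reordering stages never reshuffles another
## stage's draws.

#' Derive a deterministic substream seed
#'
#' Combines a master seed with a stage label by a fixed polynomial string
#' hash; the result is a valid 32-bit R seed.
#'
#' @param seed master integer seed.
#' @param label stage label, e.g. \code{"shard3"} or \code{"init"}.
#' @return integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(label)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Read a YAML run configuration
#'
#' Known top-level sections: \code{grid} (nx, ny, pixel_size), \code{tip}
#' (R, Theta), \code{scan_noise} (the \linkS4class{ScanNoiseParams} fields),
#' \code{radii} (per-residue table), and free-form module sections. Missing
#' sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return named list with parsed objects: \code{grid}
#'   (\linkS4class{ImageGrid}), \code{tip} (\linkS4class{TipModel}),
#'   \code{scanNoise} (\linkS4class{ScanNoiseParams}), plus the raw list as
#'   \code{raw}.
#' @export
readRunConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  g <- raw$grid %||% list()
  grid <- ImageGrid(nx = g$nx %||% 36L, ny = g$ny %||% 36L,
                    pixelSize = g$pixel_size %||% 0.8)
  tp <- raw$tip %||% list()
  tip <- TipModel(radius = tp$R %||% 1, halfAngle = tp$Theta %||% 10)
  sn <- raw$scan_noise %||% list()
  scanNoise <- ScanNoiseParams(
    s = sn$s %||% 1, w = sn$w %||% 1,
    varX = sn$var_x %||% 0.81, varY = sn$var_y %||% 0.81,
    varPhi = sn$var_phi %||% 6.25, varTheta = sn$var_theta %||% 6.25,
    varPsi = sn$var_psi %||% 25,
    drMax = sn$dr_max %||% 1.2, dphiMax = sn$dphi_max %||% 5,
    dthetaMax = sn$dtheta_max %||% 5, dpsiMax = sn$dpsi_max %||% 10)
  list(grid = grid, tip = tip, scanNoise = scanNoise, raw = raw)
}

#' Write a provenance sidecar
#'
#' Records enough to regenerate an output directory: the seed, the
#' configuration (hashed and inlined), package and R versions, and a
#' timestamp.
#'
#' @param dir output directory.
#' @param seed the seed used.
#' @param config the configuration list (or NULL).
#' @param extra optional named list of extra fields.
#' @return the provenance file path, invisibly.
#' @export
writeProvenance <- function(dir, seed, config = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  prov <- c(list(
    seed = seed,
    config_sha = .stringHash(as.character(cfgJson)),
    config = config,
    package = as.character(utils::packageVersion("afmstate")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.stringHash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}
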