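## Height-image file I/O.
##
## AFM height maps are exchanged as 32-bit float grayscale TIFF in physical
## units (nm) or as headerless CSV. The TIFF codec here is deliberately
## minimal — single image, uncompressed, little-endian, SampleFormat = IEEE
## float — because height data must round-trip losslessly in nm; it also
## reads equivalent float TIFFs produced by common scientific writers
## (multi-strip, SHORT or LONG tag types).
##
## Orientation: TIFF rows run top-to-bottom; HeightImage row 1 is the bottom
## scan line. The writer flips rows so files display upright, and the reader
## flips back, making write/read an exact identity.

.tiff_tag <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

#' Write a height image
#'
#' @param img a \linkS4class{HeightImage}.
#' @param path output path; format chosen by extension (.tif/.tiff or .csv).
#' @return \code{path}, invisibly.
#' @export
writeHeightImage <- function(img, path) {
  stopifnot(is(img, "HeightImage"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- img@values
    lines <- apply(m, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = ","))
    writeLines(lines, path)
    return(invisible(path))
  }
  .write_float_tiff(img@values, path)
  invisible(path)
}

.write_float_tiff <- function(values, path) {
  ny <- nrow(values); nx <- ncol(values)
  pix <- as.numeric(t(values[ny:1L, , drop = FALSE]))  # top row first
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  dataOffset <- 8L
  nbytes <- 4L * nx * ny
  ifdOffset <- dataOffset + nbytes
  writeBin(ifdOffset, con, size = 4, endian = "little")
  writeBin(pix, con, size = 4, endian = "little")
  tags <- list(
    .tiff_tag(256L, 4L, 1L, nx),          # ImageWidth
    .tiff_tag(257L, 4L, 1L, ny),          # ImageLength
    .tiff_tag(258L, 3L, 1L, 32L),         # BitsPerSample
    .tiff_tag(259L, 3L, 1L, 1L),          # Compression: none
    .tiff_tag(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
    .tiff_tag(273L, 4L, 1L, dataOffset),  # StripOffsets
    .tiff_tag(277L, 3L, 1L, 1L),          # SamplesPerPixel
    .tiff_tag(278L, 4L, 1L, ny),          # RowsPerStrip
    .tiff_tag(279L, 4L, 1L, nbytes),      # StripByteCounts
    .tiff_tag(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg$tag, con, size = 2, endian = "little")
    writeBin(tg$type, con, size = 2, endian = "little")
    writeBin(tg$count, con, size = 4, endian = "little")
    if (tg$type == 3L) {  # SHORT, inline left-justified
      writeBin(tg$value, con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg$value, con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
}

#' Read a height image
#'
#' @param path a float TIFF or headerless CSV file holding heights in nm.
#' @param pixelSize nm per pixel used to reconstruct the grid (images carry
#'   no grid metadata; 0.8 nm is the working default).
#' @return A \linkS4class{HeightImage}.
#' @export
readHeightImage <- function(path, pixelSize = 0.8) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- lapply(readLines(path), function(l)
      as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]]))
    m <- do.call(rbind, rows)
    return(HeightImage(m, ImageGrid(nx = ncol(m), ny = nrow(m),
                                    pixelSize = pixelSize)))
  }
  m <- .read_float_tiff(path)
  HeightImage(m, ImageGrid(nx = ncol(m), ny = nrow(m), pixelSize = pixelSize))
}

.read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file: ", path)
  ifd <- u32(4)
  nEntries <- u16(ifd)
  fields <- list()
  for (e in seq_len(nEntries)) {
    off <- ifd + 2 + (e - 1) * 12
    tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
    size <- c(1, 1, 2, 4, 8)[type]
    vals <- if (count * size <= 4) {
      vapply(seq_len(count), function(i) {
        if (type == 3L) u16(off + 8 + (i - 1) * 2) else u32(off + 8 + (i - 1) * 4)
      }, numeric(1))
    } else {
      voff <- u32(off + 8)
      vapply(seq_len(count), function(i) {
        if (type == 3L) u16(voff + (i - 1) * 2) else u32(voff + (i - 1) * 4)
      }, numeric(1))
    }
    fields[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- fields[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  nx <- need(256); ny <- need(257)
  if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
  if (need(258, 32)[1] != 32 || need(339, 1)[1] != 3)
    stop("only 32-bit float samples are supported: ", path)
  if (need(277, 1) != 1) stop("only single-sample TIFF supported: ", path)
  offsets <- need(273); counts <- need(279)
  pix <- numeric(0)
  for (s in seq_along(offsets)) {
    conn <- rawConnection(raw[offsets[s] + seq_len(counts[s])])
    pix <- c(pix, readBin(conn, "numeric", counts[s] / 4, size = 4,
                          endian = "little"))
    close(conn)
  }
  m <- matrix(pix, nrow = ny, ncol = nx, byrow = TRUE)
  m[ny:1L, , drop = FALSE]  # back to bottom-row-first
}
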