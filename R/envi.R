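# ENVI header + flat binary I/O. The format is a text header (key = value,
# with {}-bracketed lists) next to a raw binary whose layout is declared by
# `interleave` (bsq/bil/bip) and `data type`. Only the subset needed for
# reflectance cubes is supported.

.ENVI_TYPES <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# Parse an ENVI header file into a named list of character values;
# {}-bracketed lists are returned as numeric vectors when they parse as such.
.parseEnviHeader <- function(headerPath) {
  lines <- readLines(headerPath, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE) && i < n) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
      items <- trimws(strsplit(val, ",")[[1]])
      items <- items[nzchar(items)]
      nums <- suppressWarnings(as.numeric(items))
      out[[tolower(key)]] <- if (!anyNA(nums)) nums else items
    } else {
      out[[tolower(key)]] <- val
    }
    i <- i + 1L
  }
  out
}

# Locate the binary image file belonging to a header.
.enviDataPath <- function(headerPath) {
  stem <- sub("\\.hdr$", "", headerPath)
  for (cand in c(stem, paste0(stem, ".dat"), paste0(stem, ".img"),
                 paste0(stem, ".raw"), paste0(stem, ".bsq"))) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  stop("no binary image file found next to header: ", headerPath)
}

#' Read an ENVI-format hyperspectral cube
#'
#' Parses the text header (dimensions, data type, interleave, byte order,
#' wavelength list, optional reflectance scale factor) and loads the raw
#' binary, normalising any interleave to (row, col, band) order. When the
#' header declares a \code{reflectance scale factor}, values are divided by
#' it so the cube always holds dimensionless fractions.
#'
#' @param headerPath path to the \code{.hdr} file; the binary is found next
#'   to it (same stem, or stem + .dat/.img/.raw/.bsq).
#' @param originNote provenance tag stored on the cube (default: the header
#'   path).
#' @param permissive passed to [SpectralCube()]; allow reflectance outside
#'   [0, 1.5].
#' @return A [SpectralCube-class].
#' @examples
#' cube <- SpectralCube(array(runif(2 * 3 * 4), c(2, 3, 4)),
#'                      c(500, 550, 600, 650))
#' hdr <- file.path(tempdir(), "tiny.hdr")
#' writeEnviCube(cube, hdr)
#' back <- readEnviCube(hdr)
#' all.equal(reflectance(back), reflectance(cube))
#' @export
readEnviCube <- function(headerPath, originNote = headerPath,
                         permissive = FALSE) {
  if (!file.exists(headerPath)) stop("header file not found: ", headerPath)
  hdr <- .parseEnviHeader(headerPath)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- need[!need %in% names(hdr)]
  if (length(miss))
    stop("ENVI header missing required field(s): ", paste(miss, collapse = ", "))
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header has no wavelength list; cannot resolve bands")
  S <- as.integer(hdr$samples); L <- as.integer(hdr$lines)
  B <- as.integer(hdr$bands)
  wl <- as.numeric(hdr$wavelength)
  if (length(wl) != B)
    stop("wavelength list length (", length(wl), ") != bands (", B, ")")
  tp <- .ENVI_TYPES[[as.character(as.integer(hdr[["data type"]]))]]
  if (is.null(tp)) stop("unsupported ENVI data type: ", hdr[["data type"]])
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1L) "big" else "little"
  offset <- if (!is.null(hdr[["header offset"]]))
    as.integer(hdr[["header offset"]]) else 0L
  dataPath <- .enviDataPath(headerPath)
  nExpected <- as.double(S) * L * B
  fsize <- file.size(dataPath)
  if (fsize - offset != nExpected * tp$size)
    stop(sprintf(
      "binary size (%d bytes after offset) does not match header dims %d x %d x %d at %d bytes/value",
      fsize - offset, L, S, B, tp$size))
  con <- file(dataPath, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  vals <- readBin(con, tp$what, n = nExpected, size = tp$size,
                  signed = tp$signed, endian = endian)
  vals <- as.double(vals)
  arr <- switch(tolower(hdr$interleave),
    bsq = aperm(array(vals, c(S, L, B)), c(2, 1, 3)),
    bil = aperm(array(vals, c(S, B, L)), c(3, 1, 2)),
    bip = aperm(array(vals, c(B, S, L)), c(3, 2, 1)),
    stop("unknown interleave: ", hdr$interleave)
  )
  sf <- hdr[["reflectance scale factor"]]
  if (!is.null(sf) && as.numeric(sf) > 0 && as.numeric(sf) != 1)
    arr <- arr / as.numeric(sf)
  SpectralCube(arr, wl, originNote = originNote, permissive = permissive)
}

#' Write a SpectralCube as ENVI header + binary
#'
#' @param cube a [SpectralCube-class].
#' @param headerPath output \code{.hdr} path; the binary is written to the
#'   same stem with a \code{.dat} suffix.
#' @param interleave one of \code{"bsq"}, \code{"bil"}, \code{"bip"}.
#' @param dataType ENVI data type code: 4 (float32) or 5 (float64, default;
#'   value-exact round trips).
#' @return Invisibly, the header path.
#' @export
writeEnviCube <- function(cube, headerPath, interleave = c("bsq", "bil", "bip"),
                          dataType = 5L) {
  stopifnot(is(cube, "SpectralCube"))
  interleave <- match.arg(interleave)
  tp <- .ENVI_TYPES[[as.character(as.integer(dataType))]]
  if (is.null(tp) || tp$what != "double")
    stop("dataType must be 4 (float32) or 5 (float64)")
  arr <- reflectance(cube)
  d <- dim(arr)  # rows(L) x cols(S) x bands(B)
  vals <- switch(interleave,
    bsq = as.vector(aperm(arr, c(2, 1, 3))),
    bil = as.vector(aperm(arr, c(2, 3, 1))),
    bip = as.vector(aperm(arr, c(3, 2, 1)))
  )
  dataPath <- paste0(sub("\\.hdr$", "", headerPath), ".dat")
  con <- file(dataPath, "wb")
  writeBin(vals, con, size = tp$size, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    sprintf("description = { %s }", originNote(cube)),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(dataType)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(format(wavelengths(cube), trim = TRUE, digits = 10),
                  collapse = ", "))
  )
  writeLines(hdr, headerPath)
  invisible(headerPath)
}

#' Export a class-label map as a single-band integer ENVI raster
#'
#' @param map a [PixelClassMap-class] or [VegetationMask-class] (written as
#'   0/1).
#' @param headerPath output \code{.hdr} path.
#' @return Invisibly, the header path.
#' @export
writeEnviClassMap <- function(map, headerPath) {
  lab <- if (is(map, "PixelClassMap")) labelMatrix(map)
         else if (is(map, "VegetationMask")) {
           m <- maskMatrix(map); storage.mode(m) <- "integer"; m
         } else stop("map must be a PixelClassMap or VegetationMask")
  dataPath <- paste0(sub("\\.hdr$", "", headerPath), ".dat")
  con <- file(dataPath, "wb")
  writeBin(as.integer(t(lab)), con, size = 4L, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = { class labels (-1 = unlabelled) }",
    sprintf("samples = %d", ncol(lab)),
    sprintf("lines = %d", nrow(lab)),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 3",
    "interleave = bsq",
    "byte order = 0"
  )
  writeLines(hdr, headerPath)
  invisible(headerPath)
}
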