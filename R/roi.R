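#' Nearest-band lookup
#'
#' Returns the ordinal of the band whose center wavelength is nearest the
#' target. Ties are broken toward the lower wavelength. Errors when the
#' nearest center is farther than the tolerance.
#'
#' @param cube a [SpectralCube-class], or a numeric wavelength vector.
#' @param targetNm target wavelength (nm).
#' @param tolNm tolerance (nm); default one sampling interval (the median
#'   spacing of the wavelength grid).
#' @return Integer band index (1-based).
#' @examples
#' bandIndex(c(548.9, 551.1), 550)  # tie -> lower wavelength
#' @export
bandIndex <- function(cube, targetNm, tolNm = NULL) {
  wl <- if (is(cube, "SpectralCube")) wavelengths(cube) else as.numeric(cube)
  if (is.null(tolNm))
    tolNm <- if (length(wl) > 1) stats::median(diff(wl)) else Inf
  if (tolNm <= 0) stop("tolNm must be > 0")
  d <- abs(wl - targetNm)
  i <- which.min(d)  # which.min takes the first minimum = lower wavelength
  if (d[i] > tolNm)
    stop(sprintf(
      "no band within %.3g nm of %.6g nm (nearest available: %.6g nm)",
      tolNm, targetNm, wl[i]))
  i
}

#' Define a region of interest
#'
#' A height x width pixel window anchored at a center pixel. For odd sizes
#' the window is symmetric; for even sizes (such as the standard 30 x 30 =
#' 900-pixel sampling window) the center sits at the upper-left pixel of the
#' central 2 x 2 block, i.e. rows \code{row - floor((h-1)/2)} through
#' \code{row + ceiling((h-1)/2)}.
#'
#' @param row,col 1-based center pixel coordinates.
#' @param height,width window size in pixels (>= 1); default 30 x 30.
#' @return A list of class \code{"Roi"}.
#' @export
roi <- function(row, col, height = 30L, width = 30L) {
  row <- as.integer(row); col <- as.integer(col)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("height and width must be >= 1")
  if (row < 1L || col < 1L) stop("row and col must be >= 1")
  structure(list(row = row, col = col, height = height, width = width),
            class = "Roi")
}

# Window index ranges of an ROI, before clipping to image bounds.
.roiRanges <- function(r) {
  list(rows = (r$row - (r$height - 1L) %/% 2L):(r$row + r$height %/% 2L),
       cols = (r$col - (r$width - 1L) %/% 2L):(r$col + r$width %/% 2L))
}

#' Extract an ROI sub-cube
#'
#' Cuts the ROI window out of a cube. Windows overlapping the image edge are
#' clipped and the result carries the clipped flag; the center must lie
#' inside the cube.
#'
#' @param cube a [SpectralCube-class].
#' @param r an ROI from [roi()].
#' @return A [SpectralCube-class] of at most \code{height x width} pixels.
#' @examples
#' cube <- SpectralCube(array(0.2, c(100, 100, 3)), c(500, 550, 600))
#' sub <- extractRoi(cube, roi(50, 50))
#' prod(spatialDims(sub))  # 900 pixels
#' @export
extractRoi <- function(cube, r) {
  stopifnot(is(cube, "SpectralCube"), inherits(r, "Roi"))
  d <- spatialDims(cube)
  if (r$row > d[1] || r$col > d[2])
    stop(sprintf("ROI center (%d, %d) outside cube (%d x %d)",
                 r$row, r$col, d[1], d[2]))
  rg <- .roiRanges(r)
  rows <- rg$rows[rg$rows >= 1L & rg$rows <= d[1]]
  cols <- rg$cols[rg$cols >= 1L & rg$cols <= d[2]]
  clip <- length(rows) < r$height || length(cols) < r$width
  sub <- reflectance(cube)[rows, cols, , drop = FALSE]
  new("SpectralCube", reflectance = sub, wavelengths = wavelengths(cube),
      originNote = originNote(cube), clipped = clip)
}

#' Read a sample-point table
#'
#' CSV with columns \code{sample_id,row,col,lnc}: ground sampling points with
#' 1-based pixel coordinates of the sampling location and the measured leaf
#' nitrogen content (LNC; default unit g per kg dry mass, declared by the
#' table's provenance). Duplicate ids, non-numeric or non-positive LNC are
#' rejected with the offending row number.
#'
#' @param csvPath path to the CSV (header row required).
#' @return data.frame with columns sample_id (character), row, col (integer),
#'   lnc (numeric).
#' @export
readSampleTable <- function(csvPath) {
  df <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "row", "col", "lnc")
  miss <- need[!need %in% names(df)]
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop("duplicate sample_id at row(s): ", paste(dup, collapse = ", "))
  lnc <- suppressWarnings(as.numeric(df$lnc))
  bad <- which(is.na(lnc) | lnc <= 0)
  if (length(bad))
    stop("non-numeric or non-positive lnc at row(s): ",
         paste(bad, collapse = ", "))
  df$lnc <- lnc
  df$row <- as.integer(df$row); df$col <- as.integer(df$col)
  if (any(is.na(df$row)) || any(is.na(df$col)) ||
      any(df$row < 1L) || any(df$col < 1L))
    stop("row/col must be positive integers (1-based pixel coordinates)")
  df[, need]
}
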