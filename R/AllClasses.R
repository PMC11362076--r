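#' @import methods
NULL

#' SpectralCube: a hyperspectral reflectance cube
#'
#' A 3-D grid of dimensionless reflectance values indexed (row, col, band),
#' together with the strictly increasing vector of band-center wavelengths in
#' nanometres. This is the object every pipeline stage transforms. Typical
#' cubes cover 400--1,000 nm at a 2.2 nm sampling interval.
#'
#' @slot reflectance numeric array, dim = c(rows, cols, bands).
#' @slot wavelengths numeric, band-center wavelengths (nm), strictly
#'   increasing, length equal to the band count.
#' @slot originNote free-text provenance tag.
#' @slot clipped logical; \code{TRUE} when the cube is an edge-clipped
#'   region-of-interest extract.
#'
#' @seealso [SpectralCube()] for the validating constructor,
#'   [readEnviCube()] to load a cube from disk.
#' @export
setClass("SpectralCube",
  representation(
    reflectance = "array",
    wavelengths = "numeric",
    originNote  = "character",
    clipped     = "logical"
  ),
  prototype(originNote = "", clipped = FALSE)
)

setValidity("SpectralCube", function(object) {
  d <- dim(object@reflectance)
  msgs <- character()
  if (length(d) != 3L)
    msgs <- c(msgs, "reflectance must be a 3-D array (row, col, band)")
  else {
    if (d[1] < 1L || d[2] < 1L)
      msgs <- c(msgs, "row/col dimensions must be >= 1")
    if (length(object@wavelengths) != d[3])
      msgs <- c(msgs, "length(wavelengths) must equal the band count")
  }
  if (length(object@wavelengths) &&
      any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (anyNA(object@reflectance) || any(!is.finite(object@reflectance)))
    msgs <- c(msgs, "reflectance values must all be finite")
  if (length(msgs)) msgs else TRUE
})

#' VegetationMask: per-pixel vegetation flag
#'
#' Boolean raster marking which pixels of a [SpectralCube] are vegetation
#' (sunlit or shaded canopy), as produced by [vegetationMask()].
#'
#' @slot mask logical matrix, same spatial dims as the source cube;
#'   \code{TRUE} = vegetation.
#' @slot methodNote how the mask was derived.
#' @export
setClass("VegetationMask",
  representation(mask = "matrix", methodNote = "character"),
  prototype(methodNote = "")
)

setValidity("VegetationMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
})

#' LevelScheme: intensity level boundaries
#'
#' The boundary definition of an n-level binning of green-band (550 nm)
#' reflectance. Bins are half-open \code{[edge_i, edge_{i+1})} except the last,
#' which is closed on the right so the maximum value lands in the top level.
#'
#' @slot nLevels integer number of levels (default 10).
#' @slot mode \code{"equal_width"} or \code{"quantile"}.
#' @slot edges numeric vector of \code{nLevels + 1} strictly increasing
#'   boundaries; \code{edges[1]} and \code{edges[nLevels + 1]} are the fitted
#'   lower/upper range.
#' @seealso [fitLevelScheme()], [classifyStage()]
#' @export
setClass("LevelScheme",
  representation(nLevels = "integer", mode = "character", edges = "numeric")
)

setValidity("LevelScheme", function(object) {
  msgs <- character()
  if (length(object@nLevels) != 1L || object@nLevels < 1L)
    msgs <- c(msgs, "nLevels must be a single positive integer")
  if (!object@mode %in% c("equal_width", "quantile"))
    msgs <- c(msgs, "mode must be 'equal_width' or 'quantile'")
  if (length(object@edges) != object@nLevels + 1L)
    msgs <- c(msgs, "edges must have nLevels + 1 entries")
  if (any(diff(object@edges) <= 0))
    msgs <- c(msgs, "edges must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' PixelClassMap: per-pixel level labels
#'
#' Integer label raster from one stage of the green-intensity classifier.
#' Labels run 0..nLevels-1 inside the vegetation mask and -1 outside (or, for
#' a stage-2 map, outside the retained stage-1 classes). Printed labels carry
#' the stage prefix, e.g. "1-4" or "2-3".
#'
#' @slot labels integer matrix; -1 = unlabelled.
#' @slot scheme the [LevelScheme] that produced the labels.
#' @slot stage integer, 1 or 2.
#' @slot labelPrefix character, \code{"1-"} or \code{"2-"}.
#' @seealso [classifyStage()], [cascadeClassify()], [classPixelStats()]
#' @export
setClass("PixelClassMap",
  representation(
    labels = "matrix",
    scheme = "LevelScheme",
    stage  = "integer",
    labelPrefix = "character"
  )
)

setValidity("PixelClassMap", function(object) {
  msgs <- character()
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be an integer matrix")
  lab <- object@labels
  if (length(lab) && (min(lab) < -1L || max(lab) >= object@scheme@nLevels))
    msgs <- c(msgs, "labels must lie in {-1, 0..nLevels-1}")
  if (!object@stage %in% c(1L, 2L))
    msgs <- c(msgs, "stage must be 1 or 2")
  if (length(msgs)) msgs else TRUE
})
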