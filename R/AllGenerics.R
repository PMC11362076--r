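#' @rdname SpectralCube-accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectralCube-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralCube-accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname SpectralCube-accessors
#' @export
setGeneric("spatialDims", function(x) standardGeneric("spatialDims"))

#' @rdname SpectralCube-accessors
#' @export
setGeneric("originNote", function(x) standardGeneric("originNote"))

#' @rdname SpectralCube-accessors
#' @export
setGeneric("isClipped", function(x) standardGeneric("isClipped"))

#' @rdname VegetationMask-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname LevelScheme-accessors
#' @export
setGeneric("levelEdges", function(x) standardGeneric("levelEdges"))

#' @rdname LevelScheme-accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname PixelClassMap-accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname PixelClassMap-accessors
#' @export
setGeneric("levelScheme", function(x) standardGeneric("levelScheme"))

#' @rdname PixelClassMap-accessors
#' @export
setGeneric("classStage", function(x) standardGeneric("classStage"))

#' Per-class pixel counts and percentages
#'
#' @param x a [PixelClassMap] or [VegetationMask].
#' @param ... unused.
#' @return A data.frame with one row per label (plus a totals row): columns
#'   \code{label}, \code{pixels}, \code{percent}. Percentages are of the total
#'   pixel count and sum to 100 up to rounding.
#' @export
setGeneric("classPixelStats", function(x, ...) standardGeneric("classPixelStats"))
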