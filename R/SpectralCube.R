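#' Construct a SpectralCube
#'
#' Validating constructor. Reflectance is stored as dimensionless fractions;
#' values below 0 or above 1.5 are rejected unless \code{permissive = TRUE}
#' (physically implausible reflectance usually signals a missing scale
#' factor).
#'
#' @param reflectance numeric array, dim = c(rows, cols, bands).
#' @param wavelengths numeric vector of band-center wavelengths (nm),
#'   strictly increasing.
#' @param originNote free-text provenance tag.
#' @param permissive logical; allow reflectance outside [0, 1.5].
#' @param clipped logical; marks an edge-clipped ROI extract.
#' @return A [SpectralCube-class] object.
#' @examples
#' cube <- SpectralCube(array(0.3, c(2, 2, 4)), c(500, 550, 600, 650))
#' nBands(cube)
#' @export
SpectralCube <- function(reflectance, wavelengths, originNote = "",
                         permissive = FALSE, clipped = FALSE) {
  if (is.matrix(reflectance))
    reflectance <- array(reflectance, c(dim(reflectance), 1L))
  storage.mode(reflectance) <- "double"
  if (!permissive) {
    if (anyNA(reflectance) || any(!is.finite(reflectance)))
      stop("reflectance contains non-finite values")
    rng <- range(reflectance)
    if (rng[1] < 0 || rng[2] > 1.5)
      stop(sprintf(
        "reflectance outside [0, 1.5] (range %.4g..%.4g); pass permissive = TRUE to accept",
        rng[1], rng[2]))
  }
  new("SpectralCube", reflectance = reflectance,
      wavelengths = as.numeric(wavelengths),
      originNote = originNote, clipped = clipped)
}

#' Accessors for SpectralCube
#'
#' @param x a [SpectralCube-class].
#' @name SpectralCube-accessors
#' @return \code{reflectance}: the 3-D array; \code{wavelengths}: the nm
#'   vector; \code{nBands}: band count; \code{spatialDims}: c(rows, cols);
#'   \code{originNote}: provenance tag; \code{isClipped}: clipped flag.
NULL

#' @rdname SpectralCube-accessors
#' @export
setMethod("reflectance", "SpectralCube", function(x) x@reflectance)

#' @rdname SpectralCube-accessors
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname SpectralCube-accessors
#' @export
setMethod("nBands", "SpectralCube", function(x) dim(x@reflectance)[3])

#' @rdname SpectralCube-accessors
#' @export
setMethod("spatialDims", "SpectralCube", function(x) dim(x@reflectance)[1:2])

#' @rdname SpectralCube-accessors
#' @export
setMethod("originNote", "SpectralCube", function(x) x@originNote)

#' @rdname SpectralCube-accessors
#' @export
setMethod("isClipped", "SpectralCube", function(x) x@clipped)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@reflectance)
  wl <- object@wavelengths
  cat("SpectralCube:", d[1], "x", d[2], "pixels,", d[3], "bands\n")
  cat(sprintf("  wavelengths: %.1f..%.1f nm (median step %.2f nm)\n",
              wl[1], wl[length(wl)],
              if (length(wl) > 1) stats::median(diff(wl)) else NA_real_))
  if (nzchar(object@originNote)) cat("  origin:", object@originNote, "\n")
  if (object@clipped) cat("  [edge-clipped ROI]\n")
})

#' @rdname VegetationMask-accessors
#' @param x a [VegetationMask-class].
#' @export
setMethod("maskMatrix", "VegetationMask", function(x) x@mask)

setMethod("show", "VegetationMask", function(object) {
  n <- length(object@mask)
  cat(sprintf("VegetationMask: %d x %d pixels, %.2f%% vegetation\n",
              nrow(object@mask), ncol(object@mask),
              100 * sum(object@mask) / n))
  if (nzchar(object@methodNote)) cat("  method:", object@methodNote, "\n")
})

#' @rdname LevelScheme-accessors
#' @param x a [LevelScheme-class].
#' @export
setMethod("levelEdges", "LevelScheme", function(x) x@edges)

#' @rdname LevelScheme-accessors
#' @export
setMethod("nLevels", "LevelScheme", function(x) x@nLevels)

setMethod("show", "LevelScheme", function(object) {
  cat(sprintf("LevelScheme: %d %s levels on [%.4g, %.4g]\n",
              object@nLevels, object@mode,
              object@edges[1], object@edges[length(object@edges)]))
})

#' @rdname PixelClassMap-accessors
#' @param x a [PixelClassMap-class].
#' @export
setMethod("labelMatrix", "PixelClassMap", function(x) x@labels)

#' @rdname PixelClassMap-accessors
#' @export
setMethod("levelScheme", "PixelClassMap", function(x) x@scheme)

#' @rdname PixelClassMap-accessors
#' @export
setMethod("classStage", "PixelClassMap", function(x) x@stage)

setMethod("show", "PixelClassMap", function(object) {
  lab <- object@labels
  cat(sprintf("PixelClassMap (stage %d): %d x %d pixels, %d labelled\n",
              object@stage, nrow(lab), ncol(lab), sum(lab >= 0L)))
  tab <- table(lab[lab >= 0L])
  if (length(tab)) {
    nm <- paste0(object@labelPrefix, names(tab))
    cat("  ", paste(sprintf("%s:%d", nm, as.integer(tab)), collapse = " "),
        "\n")
  }
})
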