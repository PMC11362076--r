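# The 20 vegetation indices screened against leaf nitrogen content. Each is
# an arithmetic expression over R_lambda, the reflectance at the band nearest
# lambda nm. The generic red/green/NIR anchors (used by R/G and MACI) default
# to 670/550/800 nm, the anchors the other indices use, and are configurable.

#' Vegetation index registry
#'
#' @param redNm,greenNm,nirNm band anchors for the generic R_Red, R_green and
#'   R_NIR terms (defaults 670, 550, 800 nm).
#' @return Named list; each element has \code{wavelengths} (nm the formula
#'   needs) and \code{fn}, a function of a lookup \code{R(nm)}. The names are
#'   the 20 index identifiers: ZMI, VOG1, GRVI, RVI, RG ("R/G"), MACI, RECI,
#'   GMI, GNDVI, NDVI, IPVI, MTCI, SIPI, mSR705, NDVI801, RENDVI, mND705,
#'   NPQI, HNDVI, SAVI.
#' @details Formula notes: NDVI is the (810, 560) variant as used here; the
#'   conventional (800-ish, 670-ish) pair is covered by HNDVI (827, 668).
#'   GMI is (R750/R720) - 1. Zero denominators yield an NA missing-value
#'   marker rather than an error.
#' @export
viRegistry <- function(redNm = 670, greenNm = 550, nirNm = 800) {
  list(
    ZMI   = list(wavelengths = c(750, 710),
                 fn = function(R) R(750) / R(710)),
    VOG1  = list(wavelengths = c(740, 720),
                 fn = function(R) R(740) / R(720)),
    GRVI  = list(wavelengths = c(800, 550),
                 fn = function(R) R(800) / R(550)),
    RVI   = list(wavelengths = c(800, 700),
                 fn = function(R) R(800) / R(700)),
    RG    = list(wavelengths = c(redNm, greenNm),
                 fn = function(R) R(redNm) / R(greenNm)),
    MACI  = list(wavelengths = c(nirNm, greenNm),
                 fn = function(R) R(nirNm) / R(greenNm)),
    RECI  = list(wavelengths = c(750, 550),
                 fn = function(R) R(750) / R(550) - 1),
    GMI   = list(wavelengths = c(750, 720),
                 fn = function(R) R(750) / R(720) - 1),
    GNDVI = list(wavelengths = c(780, 550),
                 fn = function(R) (R(780) - R(550)) / (R(780) + R(550))),
    NDVI  = list(wavelengths = c(810, 560),
                 fn = function(R) (R(810) - R(560)) / (R(810) + R(560))),
    IPVI  = list(wavelengths = c(800, 670),
                 fn = function(R) R(800) / (R(800) + R(670))),
    MTCI  = list(wavelengths = c(754, 709, 681),
                 fn = function(R) (R(754) - R(709)) / (R(709) - R(681))),
    SIPI  = list(wavelengths = c(800, 450),
                 fn = function(R) (R(800) - R(450)) / (R(800) + R(450))),
    mSR705 = list(wavelengths = c(750, 705, 445),
                 fn = function(R) (R(750) - R(445)) / (R(705) + R(445))),
    NDVI801 = list(wavelengths = c(801, 550),
                 fn = function(R) (R(801) - R(550)) / (R(801) + R(550))),
    RENDVI = list(wavelengths = c(750, 705),
                 fn = function(R) (R(750) - R(705)) / (R(750) + R(705))),
    mND705 = list(wavelengths = c(750, 705, 445),
                 fn = function(R) (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445))),
    NPQI  = list(wavelengths = c(415, 435),
                 fn = function(R) (R(415) - R(435)) / (R(415) + R(435))),
    HNDVI = list(wavelengths = c(827, 668),
                 fn = function(R) (R(827) - R(668)) / (R(827) + R(668))),
    SAVI  = list(wavelengths = c(800, 670),
                 fn = function(R) 1.5 * (R(800) - R(670)) /
                                  (R(800) - R(670) + 0.5))
  )
}

#' Names of the 20 vegetation indices
#' @return Character vector in registry order.
#' @export
viNames <- function() names(viRegistry())

# Reflectance lookup closure over a spectrum (nearest band within tolerance).
.spectrumLookup <- function(spectrum, wl, tolNm = NULL) {
  function(nm) spectrum[bandIndex(wl, nm, tolNm = tolNm)]
}

#' Compute one vegetation index from a spectrum
#'
#' Evaluates the index formula with \code{R_lambda} taken as the reflectance
#' at the band nearest \code{lambda} (within one sampling interval). A zero
#' denominator (e.g. MTCI when R709 = R681) yields \code{NA} with a message,
#' not an error.
#'
#' @param spectrum numeric reflectance vector.
#' @param wl wavelength grid of the spectrum (nm).
#' @param name index name (see [viNames()]).
#' @param registry optionally, a custom [viRegistry()].
#' @return Numeric index value (or NA).
#' @examples
#' wl <- seq(400, 1000, by = 2.2)
#' sp <- rep(0.3, length(wl))
#' computeIndex(sp, wl, "NDVI")   # 0: symmetric difference
#' @export
computeIndex <- function(spectrum, wl, name, registry = viRegistry()) {
  def <- registry[[name]]
  if (is.null(def)) stop("unknown index: ", name)
  R <- .spectrumLookup(spectrum, wl)
  val <- def$fn(R)
  if (!is.finite(val)) {
    message("index ", name, ": zero denominator or non-finite value; NA")
    return(NA_real_)
  }
  val
}

#' Compute all registered indices from one spectrum
#'
#' @inheritParams computeIndex
#' @return Named numeric vector over the registry.
#' @export
computeIndices <- function(spectrum, wl, registry = viRegistry()) {
  vapply(names(registry),
         function(nm) computeIndex(spectrum, wl, nm, registry),
         numeric(1))
}

#' Build a sample x index table for one pixel class and one pretreatment
#'
#' For each sample point: extract its ROI, pretreat the pixel spectra,
#' average the spectra of the ROI pixels carrying the requested label(s), and
#' evaluate all indices on the mean spectrum. Samples whose ROI holds no
#' pixel with the label are dropped (and reported via message) rather than
#' emitted as NaN rows.
#'
#' @param cube a [SpectralCube-class] (full scene).
#' @param map a [PixelClassMap-class] or [VegetationMask-class].
#' @param samples data.frame from [readSampleTable()] (sample_id, row, col,
#'   lnc).
#' @param labels labels to retain (see [classMeanSpectrum()]).
#' @param pretreat a [preprocessSpec()] (default OS).
#' @param roiHeight,roiWidth ROI window size (default 30 x 30 = 900 pixels).
#' @param registry index registry.
#' @return data.frame with sample_id, lnc and one column per index; attributes
#'   \code{classLabel} and \code{pretreat} record the provenance.
#' @export
buildViTable <- function(cube, map, samples, labels = NULL,
                         pretreat = preprocessSpec("OS"),
                         roiHeight = 30L, roiWidth = 30L,
                         registry = viRegistry()) {
  stopifnot(is(cube, "SpectralCube"), is.data.frame(samples))
  wl <- wavelengths(cube)
  M <- if (pretreat$method == "OS") NULL
       else .preprocessMatrix(length(wl), pretreat)
  rows <- vector("list", nrow(samples))
  kept <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    r <- roi(samples$row[i], samples$col[i], roiHeight, roiWidth)
    sp <- classMeanSpectrum(cube, map, r, labels = labels)
    if (is.null(sp)) next
    # pretreating the mean equals averaging pretreated pixel spectra
    # (the smoothing operator is linear), so smooth once here
    if (!is.null(M)) sp <- drop(M %*% sp)
    rows[[i]] <- computeIndices(sp, wl, registry)
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("no sample retained any labelled pixel")
  if (any(!kept))
    message(sum(!kept), " sample(s) dropped: no labelled pixel in ROI (",
            paste(samples$sample_id[!kept], collapse = ", "), ")")
  vi <- do.call(rbind, rows[kept])
  out <- data.frame(sample_id = samples$sample_id[kept],
                    lnc = samples$lnc[kept],
                    vi, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "classLabel") <- if (is.null(labels)) "all"
                             else paste(labels, collapse = "+")
  attr(out, "pretreat") <- pretreat$method
  out
}
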