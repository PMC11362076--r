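# Vegetation masking and the two-stage 10-level green-band (550 nm)
# intensity classification that isolates sunlit canopy pixels from soil and
# leaf shadow.

# Per-pixel NIR/red ratio used for deterministic cluster seeding and for
# flagging vegetation clusters. Healthy vegetation has high near-infrared and
# low red reflectance; soil does not.
.nirRedRatio <- function(flat, wl, nirNm = 800, redNm = 670) {
  nir <- flat[, bandIndex(wl, nirNm)]
  red <- flat[, bandIndex(wl, redNm)]
  nir / pmax(red, 1e-6)
}

#' Unsupervised vegetation mask
#'
#' Partitions pixel spectra into \code{k} clusters by iterative centroid
#' assignment (k-means) with deterministic initialisation: initial centers
#' are the spectra of the pixels sitting at evenly spaced quantiles of the
#' NIR(800)/red(670) ratio, so the mask is reproducible without randomness.
#' Clusters whose mean NIR/red ratio is at least \code{minRatio} are flagged
#' vegetation; when \code{minRatio} is \code{NULL} only the single cluster
#' with the highest mean ratio is flagged.
#'
#' @param cube a [SpectralCube-class].
#' @param k cluster count (>= 2; default 3: soil, shaded and sunlit canopy
#'   separate naturally).
#' @param seed integer; kept for API symmetry - the deterministic seeding
#'   makes the result independent of it.
#' @param minRatio vegetation threshold on a cluster's mean NIR/red ratio
#'   (default 2).
#' @param iterMax k-means iteration cap.
#' @return A [VegetationMask-class].
#' @export
vegetationMask <- function(cube, k = 3L, seed = 1L, minRatio = 2,
                           iterMax = 100L) {
  stopifnot(is(cube, "SpectralCube"))
  if (k < 2L) stop("k must be >= 2")
  d <- spatialDims(cube)
  if (prod(d) < 2L) stop("degenerate cube: need at least 2 pixels")
  arr <- reflectance(cube)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = dim(arr)[3])
  ratio <- .nirRedRatio(flat, wavelengths(cube))
  if (max(apply(flat, 2, function(v) diff(range(v)))) < 1e-12) {
    warning("all pixel spectra identical; returning all-true mask")
    return(new("VegetationMask", mask = matrix(TRUE, d[1], d[2]),
               methodNote = "degenerate: identical pixels"))
  }
  ord <- order(ratio)
  qs <- ord[pmin(length(ord),
                 pmax(1L, round((seq_len(k) - 0.5) / k * length(ord))))]
  centers <- flat[qs, , drop = FALSE]
  # kmeans rejects duplicate centers; nudge any duplicates apart
  if (anyDuplicated(centers))
    centers <- centers + outer(seq_len(k), rep(1e-9, ncol(centers)))
  set.seed(as.integer(seed))
  km <- stats::kmeans(flat, centers = centers, iter.max = iterMax,
                      algorithm = "Lloyd")
  clusterRatio <- tapply(ratio, km$cluster, mean)
  veg <- if (is.null(minRatio)) {
    as.integer(names(clusterRatio)[which.max(clusterRatio)])
  } else {
    as.integer(names(clusterRatio)[clusterRatio >= minRatio])
  }
  if (!length(veg)) veg <- as.integer(names(clusterRatio)[which.max(clusterRatio)])
  m <- matrix(km$cluster %in% veg, d[1], d[2])
  new("VegetationMask", mask = m,
      methodNote = sprintf(
        "k-means (k=%d, quantile-seeded on NIR/red); vegetation clusters: %s",
        k, paste(veg, collapse = ",")))
}

#' Fit a level scheme to green-band values
#'
#' Divides observed green reflectance into \code{nLevels} intensity levels.
#' \code{equal_width} spaces the edges evenly on the observed min-max;
#' \code{quantile} places them at i/n quantiles. The last bin is closed on
#' the right; the others are half-open \code{[edge_i, edge_{i+1})}.
#'
#' @param greenValues numeric vector of green-band reflectance.
#' @param nLevels number of levels (default 10).
#' @param mode \code{"equal_width"} (default) or \code{"quantile"}.
#' @return A [LevelScheme-class].
#' @export
fitLevelScheme <- function(greenValues, nLevels = 10L,
                           mode = c("equal_width", "quantile")) {
  mode <- match.arg(mode)
  nLevels <- as.integer(nLevels)
  greenValues <- greenValues[is.finite(greenValues)]
  if (!length(greenValues)) stop("no finite green values")
  if (mode == "equal_width") {
    lo <- min(greenValues); hi <- max(greenValues)
    if (hi <= lo) stop("constant green values: equal-width levels undefined")
    edges <- seq(lo, hi, length.out = nLevels + 1L)
  } else {
    if (length(unique(greenValues)) < nLevels)
      stop("quantile mode needs at least nLevels distinct values")
    edges <- unname(stats::quantile(greenValues,
                                    probs = seq(0, 1, length.out = nLevels + 1L),
                                    type = 7))
    if (any(diff(edges) <= 0))
      stop("degenerate quantile edges (heavily tied values)")
  }
  new("LevelScheme", nLevels = nLevels, mode = mode, edges = edges)
}

# Assign levels 0..n-1 to values under a scheme; values outside [lo, hi] are
# clamped into the extreme bins (relevant only when relabelling new data with
# a stored scheme). Last bin closed on the right.
.assignLevels <- function(values, scheme) {
  edges <- scheme@edges
  n <- scheme@nLevels
  lab <- findInterval(values, edges, rightmost.closed = TRUE) - 1L
  pmin.int(pmax.int(lab, 0L), n - 1L)
}

#' One classification stage
#'
#' Fits a [LevelScheme-class] on the green-band (550 nm) reflectance of the
#' pixels selected by \code{mask} and labels each of them with its level;
#' unselected pixels get label -1. Pass a stored scheme via \code{scheme} to
#' relabel deterministically instead of refitting.
#'
#' @param cube a [SpectralCube-class].
#' @param mask a [VegetationMask-class] (stage 1) or logical matrix of pixels
#'   to classify.
#' @param nLevels,mode passed to [fitLevelScheme()].
#' @param stage 1 or 2 (sets the printed label prefix).
#' @param greenNm green band target wavelength (default 550 nm, resolved via
#'   [bandIndex()] within one sampling interval).
#' @param scheme optional pre-fitted [LevelScheme-class].
#' @return A [PixelClassMap-class].
#' @export
classifyStage <- function(cube, mask, nLevels = 10L,
                          mode = c("equal_width", "quantile"),
                          stage = 1L, greenNm = 550, scheme = NULL) {
  stopifnot(is(cube, "SpectralCube"))
  m <- if (is(mask, "VegetationMask")) maskMatrix(mask) else mask
  d <- spatialDims(cube)
  if (!identical(dim(m), d)) stop("mask dims do not match cube")
  if (!any(m)) stop("empty mask: no pixels to classify")
  g <- reflectance(cube)[, , bandIndex(cube, greenNm)]
  if (is.null(scheme))
    scheme <- fitLevelScheme(g[m], nLevels = nLevels,
                             mode = match.arg(mode))
  lab <- matrix(-1L, d[1], d[2])
  lab[m] <- .assignLevels(g[m], scheme)
  new("PixelClassMap", labels = lab, scheme = scheme,
      stage = as.integer(stage), labelPrefix = paste0(stage, "-"))
}

#' Two-stage cascade classification
#'
#' The de-interference core: vegetation pixels are binned into
#' \code{nLevels} green-intensity levels (stage 1); the pixels whose stage-1
#' label falls in \code{stage1Keep} (default levels 4 and 5, the canopy
#' candidates after dropping the shadow-contaminated low levels and the
#' soil-edge high levels) are pooled, a fresh scheme is fitted on their
#' narrowed green range, and they are re-binned into \code{nLevels} stage-2
#' levels. Downstream analysis typically retains stage-2 labels 3, 4 and 5.
#'
#' @param cube a [SpectralCube-class].
#' @param mask a [VegetationMask-class].
#' @param stage1Keep integer vector of stage-1 labels to re-classify
#'   (default \code{c(4, 5)}).
#' @param nLevels levels per stage (default 10).
#' @param mode level construction mode (both stages).
#' @param greenNm green band wavelength.
#' @return list(stage1 = [PixelClassMap-class], stage2 = [PixelClassMap-class]).
#' @export
cascadeClassify <- function(cube, mask, stage1Keep = c(4L, 5L),
                            nLevels = 10L,
                            mode = c("equal_width", "quantile"),
                            greenNm = 550) {
  mode <- match.arg(mode)
  if (!length(stage1Keep)) stop("stage1Keep must be non-empty")
  stage1 <- classifyStage(cube, mask, nLevels = nLevels, mode = mode,
                          stage = 1L, greenNm = greenNm)
  keepMask <- labelMatrix(stage1) %in% as.integer(stage1Keep)
  dim(keepMask) <- dim(labelMatrix(stage1))
  if (!any(keepMask))
    stop("stage1Keep {", paste(stage1Keep, collapse = ","),
         "} selects zero pixels")
  stage2 <- classifyStage(cube, keepMask, nLevels = nLevels, mode = mode,
                          stage = 2L, greenNm = greenNm)
  list(stage1 = stage1, stage2 = stage2)
}

.pixelStatsFromLabels <- function(lab, prefix) {
  tot <- length(lab)
  labs <- sort(unique(as.vector(lab)))
  counts <- vapply(labs, function(l) sum(lab == l), integer(1))
  nm <- ifelse(labs < 0L, "unlabelled", paste0(prefix, labs))
  df <- data.frame(label = c(nm, "total"),
                   pixels = c(counts, tot),
                   percent = round(100 * c(counts, tot) / tot, 2),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @rdname classPixelStats
#' @export
setMethod("classPixelStats", "PixelClassMap", function(x, ...) {
  .pixelStatsFromLabels(x@labels, x@labelPrefix)
})

#' @rdname classPixelStats
#' @export
setMethod("classPixelStats", "VegetationMask", function(x, ...) {
  m <- x@mask
  tot <- length(m)
  nVeg <- sum(m)
  df <- data.frame(
    label = c("vegetation", "other", "total"),
    pixels = c(nVeg, tot - nVeg, tot),
    percent = round(100 * c(nVeg, tot - nVeg, tot) / tot, 2),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
})

#' Class-restricted mean spectrum over an ROI
#'
#' Unweighted mean spectrum of the ROI pixels carrying one of the requested
#' labels. When no ROI pixel carries a requested label the function returns
#' \code{NULL} with a message (a missing-value marker - downstream tables drop
#' the row) rather than throwing.
#'
#' @param cube a [SpectralCube-class] (full scene).
#' @param map a [PixelClassMap-class] or [VegetationMask-class] aligned with
#'   the cube.
#' @param r an ROI from [roi()].
#' @param labels integer labels to retain (ignored for a mask, where all
#'   mask-true pixels are used). Default \code{NULL}: all labelled pixels
#'   (label >= 0).
#' @return Numeric mean spectrum, or \code{NULL} when no pixel qualifies.
#' @export
classMeanSpectrum <- function(cube, map, r, labels = NULL) {
  stopifnot(is(cube, "SpectralCube"), inherits(r, "Roi"))
  d <- spatialDims(cube)
  rg <- .roiRanges(r)
  rows <- rg$rows[rg$rows >= 1L & rg$rows <= d[1]]
  cols <- rg$cols[rg$cols >= 1L & rg$cols <= d[2]]
  sel <- if (is(map, "VegetationMask")) {
    maskMatrix(map)[rows, cols, drop = FALSE]
  } else {
    lm <- labelMatrix(map)[rows, cols, drop = FALSE]
    if (is.null(labels)) lm >= 0L else {
      s <- lm %in% as.integer(labels); dim(s) <- dim(lm); s
    }
  }
  if (!any(sel)) {
    message(sprintf("no pixel with requested label(s) in ROI at (%d, %d)",
                    r$row, r$col))
    return(NULL)
  }
  sub <- reflectance(cube)[rows, cols, , drop = FALSE]
  flat <- matrix(sub, nrow = length(rows) * length(cols))
  colMeans(flat[as.vector(sel), , drop = FALSE])
}
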