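# Synthetic UAV hyperspectral scenes with ground truth. The generator
# emulates the structure of a fertilizer-gradient canopy trial: plots tiled
# on a grid, each plot a canopy of sunlit and shaded leaves over soil, leaf
# spectra whose pigment features co-vary with leaf nitrogen content (LNC),
# soil/canopy edge mixtures, and per-band sensor noise. It exists so every
# pipeline stage is testable against known material labels and known LNC.

#' Scene-simulation configuration
#'
#' Defaults mirror a five-gradient nitrogen trial observed at 2.2 nm sampling
#' over 400-1000 nm: 18 plots of 36 x 36 pixels (3 x 6 layout), ~65% canopy
#' cover, about a third of canopy pixels shaded, six sampling points per plot
#' (108 samples), LNC between 28 and 46 g/kg.
#'
#' @param rows,cols scene size in pixels (defaults 108 x 216).
#' @param nPlots plot count (default 18; must tile the grid).
#' @param nLncLevels applied-N gradient count (default 5).
#' @param lncRange c(lo, hi) leaf nitrogen content in g/kg dry mass.
#' @param samplesPerPlot ground sampling points per plot (default 6).
#' @param canopyCover fraction of plot pixels that are canopy (default 0.65).
#' @param shadowFraction mean fraction of canopy pixels that are shaded
#'   (default 0.35; jittered +-0.18 per plot).
#' @param shadeFactorRange multiplicative attenuation of shaded leaves
#'   (default c(0.2, 0.5)).
#' @param noiseSd per-band additive sensor noise SD (default 0.004).
#' @param wavelengths band grid in nm (default 273 bands, 400 nm + 2.2 nm
#'   steps).
#' @param seed mandatory integer seed; the scene is a pure function of the
#'   config.
#' @return list of class "SceneConfig".
#' @export
sceneConfig <- function(rows = 108L, cols = 216L, nPlots = 18L,
                        nLncLevels = 5L, lncRange = c(28, 46),
                        samplesPerPlot = 6L, canopyCover = 0.65,
                        shadowFraction = 0.35,
                        shadeFactorRange = c(0.2, 0.5),
                        noiseSd = 0.004,
                        wavelengths = seq(400, by = 2.2, length.out = 273L),
                        seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(canopyCover > 0, canopyCover <= 1,
            shadowFraction >= 0, shadowFraction <= 1,
            lncRange[1] < lncRange[2],
            all(shadeFactorRange > 0), all(shadeFactorRange < 1))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 nPlots = as.integer(nPlots),
                 nLncLevels = as.integer(nLncLevels),
                 lncRange = as.numeric(lncRange),
                 samplesPerPlot = as.integer(samplesPerPlot),
                 canopyCover = canopyCover,
                 shadowFraction = shadowFraction,
                 shadeFactorRange = as.numeric(shadeFactorRange),
                 noiseSd = noiseSd,
                 wavelengths = as.numeric(wavelengths),
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

#' Analytic sunlit/shaded leaf spectrum
#'
#' A controllable leaf model (not a radiative-transfer model): a visible
#' baseline with Gaussian pigment absorption wells at 450 and 670 nm whose
#' depth increases with LNC (so green 550 nm reflectance decreases
#' monotonically with LNC), a logistic red edge near 720 nm, and a
#' near-infrared plateau that decreases with LNC (denser high-N canopies
#' self-shade, which also reproduces the negative sign of the observed
#' ratio-index vs. LNC correlations). Shaded leaves are the sunlit spectrum
#' times a shade factor, with slightly stronger attenuation in the NIR.
#' The red-edge inflection shifts from ~714 nm to ~724 nm as LNC rises (the
#' classical chlorophyll red-edge shift), so red-edge ratio indices carry
#' nitrogen signal.
#'
#' @param lnc leaf nitrogen content (must lie within \code{lncRange}).
#' @param wavelengths nm grid.
#' @param lncRange the admissible LNC interval used to scale the pigment
#'   response.
#' @param shaded logical.
#' @param shadeFactor multiplicative attenuation for shaded leaves (required
#'   when \code{shaded}; typically drawn from the config's range).
#' @param brightness multiplicative illumination/leaf-angle factor
#'   (default 1).
#' @param nirExtra extra fractional NIR attenuation of shade (default 0.15;
#'   the scene generator varies it per plot, since the spectral quality of
#'   shade light depends on canopy depth and sky conditions).
#' @param baseShift,plateauShift,depthShift,edgeShift additive nuisance
#'   offsets on the visible baseline, NIR plateau, pigment well depth and
#'   red-edge position (nm); the generator draws these per plot to emulate
#'   LNC-independent variation (variety, water status, growth stage).
#' @return Reflectance vector over \code{wavelengths}.
#' @export
leafSpectrum <- function(lnc, wavelengths, lncRange = c(28, 46),
                         shaded = FALSE, shadeFactor = NULL,
                         brightness = 1, nirExtra = 0.15,
                         baseShift = 0, plateauShift = 0, depthShift = 0,
                         edgeShift = 0) {
  if (lnc < lncRange[1] || lnc > lncRange[2])
    stop(sprintf("lnc %.3g outside lncRange [%g, %g]",
                 lnc, lncRange[1], lncRange[2]))
  z <- (lnc - lncRange[1]) / (lncRange[2] - lncRange[1])
  d <- max(0.02, 0.10 + 0.03 * z + depthShift)   # pigment well depth
  vis <- 0.17 + baseShift -
    d * exp(-(wavelengths - 450)^2 / (2 * 60^2)) -
    d * exp(-(wavelengths - 670)^2 / (2 * 60^2))
  edgePos <- 714 + 10 * z + edgeShift            # chlorophyll red-edge shift
  s <- 1 / (1 + exp(-(wavelengths - edgePos) / 10))
  plateau <- 0.48 - 0.10 * z + plateauShift
  refl <- (vis * (1 - s) + plateau * s) * brightness
  if (shaded) {
    if (is.null(shadeFactor)) stop("shadeFactor required for a shaded leaf")
    refl <- refl * shadeFactor * (1 - nirExtra * s)
  }
  refl
}

#' Synthetic soil spectrum
#'
#' Monotone, quasi-linear brightening from ~0.14 at 400 nm to ~0.38 at
#' 1000 nm with a small random level shift; no red edge.
#'
#' @param wavelengths nm grid.
#' @param levelShift additive brightness shift (draw it from the scene RNG).
#' @return Reflectance vector.
#' @export
soilSpectrum <- function(wavelengths, levelShift = 0) {
  0.14 + 0.24 * (wavelengths - 400) / 600 +
    0.01 * sin((wavelengths - 400) / 90) + levelShift
}

# Smoothed uniform random field on an r x c grid (box blur), used for
# spatially clumped canopy blobs and shadow patches.
.clumpField <- function(r, c, passes = 2L, radius = 2L) {
  f <- matrix(stats::runif(r * c), r, c)
  k <- 2L * radius + 1L
  for (p in seq_len(passes)) {
    # separable box blur with edge replication
    cs <- apply(f, 2, function(v) {
      padded <- c(rep(v[1], radius), v, rep(v[length(v)], radius))
      stats::filter(padded, rep(1 / k, k))[(radius + 1):(radius + length(v))]
    })
    f <- t(apply(cs, 1, function(v) {
      padded <- c(rep(v[1], radius), v, rep(v[length(v)], radius))
      stats::filter(padded, rep(1 / k, k))[(radius + 1):(radius + length(v))]
    }))
  }
  f
}

#' Generate a synthetic scene with ground truth
#'
#' Tiles the plots on the grid, assigns each plot an LNC from the gradient
#' (with replicate jitter), draws spatially clumped canopy and shadow
#' patches, mixes soil into canopy-boundary pixels, fills every pixel with
#' its material spectrum (leaf spectra driven by the plot LNC, per-pixel
#' leaf-angle brightness jitter, per-pixel shade factors), and adds per-band
#' sensor noise. Fully determined by \code{config$seed}.
#'
#' @param config a [sceneConfig()].
#' @return list: \code{cube} ([SpectralCube-class]), \code{truth} with
#'   \code{material} (matrix, "soil"/"sunlit_leaf"/"shaded_leaf"),
#'   \code{plotId} (integer matrix), \code{plotLnc} (per-plot LNC vector) and
#'   \code{samples} (data.frame sample_id, row, col, lnc, plot).
#' @export
generateScene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  set.seed(config$seed)
  wl <- config$wavelengths
  R <- config$rows; C <- config$cols; P <- config$nPlots
  # plot layout: as square a tiling as divides the grid
  layouts <- list()
  for (pr in seq_len(P)) if (P %% pr == 0L) {
    pc <- P %/% pr
    if (R %% pr == 0L && C %% pc == 0L)
      layouts[[length(layouts) + 1L]] <- c(pr, pc)
  }
  if (!length(layouts)) stop("grid too small / nPlots does not tile the grid")
  dims <- vapply(layouts, function(l) abs(l[1] - l[2]), numeric(1))
  lay <- layouts[[which.min(dims)]]
  ph <- R %/% lay[1]; pw <- C %/% lay[2]
  if (ph < 4L || pw < 4L) stop("grid too small for nPlots")

  lncLevels <- seq(config$lncRange[1], config$lncRange[2],
                   length.out = config$nLncLevels)
  plotLnc <- lncLevels[(seq_len(P) - 1L) %% config$nLncLevels + 1L] +
    stats::rnorm(P, sd = 1.0)
  plotLnc <- pmin(pmax(plotLnc, config$lncRange[1]), config$lncRange[2])
  # LNC-independent plot-level spectral nuisance (variety, water status,
  # growth stage) - keeps attainable VI-LNC correlations in a realistic
  # field regime instead of a deterministic lab one
  plotBaseShift <- stats::rnorm(P, sd = 0.004)
  plotPlateauShift <- stats::rnorm(P, sd = 0.008)
  plotDepthShift <- stats::rnorm(P, sd = 0.004)
  plotEdgeShift <- stats::rnorm(P, sd = 1.0)
  # spectral quality of shade light varies by plot (canopy depth, sky,
  # transmitted-light composition): both the depth of the long-wavelength
  # deficit and the wavelength where it sets in differ between plots
  plotNirExtra <- stats::runif(P, 0.0, 0.45)
  plotShadeEdge <- stats::runif(P, 700, 740)

  material <- matrix("soil", R, C)
  plotId <- matrix(0L, R, C)
  alphaMat <- matrix(1, R, C)        # leaf weight of mixture pixels
  brightness <- matrix(1, R, C)
  shadeF <- matrix(1, R, C)

  sampleRows <- integer(0); sampleCols <- integer(0)
  samplePlot <- integer(0)

  p <- 0L
  for (i in seq_len(lay[1])) for (j in seq_len(lay[2])) {
    p <- p + 1L
    rIdx <- ((i - 1L) * ph + 1L):(i * ph)
    cIdx <- ((j - 1L) * pw + 1L):(j * pw)
    plotId[rIdx, cIdx] <- p
    canopyField <- .clumpField(ph, pw)
    canopy <- canopyField <= stats::quantile(canopyField, config$canopyCover)
    shFrac <- min(0.9, max(0.05, config$shadowFraction +
                             stats::runif(1, -0.18, 0.18)))
    shadowField <- .clumpField(ph, pw)
    thr <- stats::quantile(shadowField[canopy], shFrac)
    shaded <- canopy & (shadowField <= thr)
    mat <- matrix("soil", ph, pw)
    mat[canopy] <- "sunlit_leaf"
    mat[shaded] <- "shaded_leaf"
    # canopy/soil boundary pixels become leaf-soil mixtures
    edge <- canopy & !shaded
    inner <- edge
    inner[-1, ] <- inner[-1, ] & canopy[-ph, ]
    inner[-ph, ] <- inner[-ph, ] & canopy[-1, ]
    inner[, -1] <- inner[, -1] & canopy[, -pw]
    inner[, -pw] <- inner[, -pw] & canopy[, -1]
    border <- edge & !inner
    alphaP <- matrix(1, ph, pw)
    alphaP[border] <- stats::runif(sum(border), 0.2, 0.8)
    mat[border & alphaP < 0.5] <- "soil"   # majority-soil mixtures
    material[rIdx, cIdx] <- mat
    alphaMat[rIdx, cIdx] <- alphaP
    brightness[rIdx, cIdx] <- matrix(stats::runif(ph * pw, 0.7, 1.1), ph, pw)
    shadeF[rIdx, cIdx] <- matrix(
      stats::runif(ph * pw, config$shadeFactorRange[1],
                   config$shadeFactorRange[2]), ph, pw)

    # sampling points: sunlit canopy pixels whose 30x30 ROI stays in-plot
    ctrR <- 15:(ph - 15); ctrC <- 15:(pw - 15)
    cand <- which(mat[ctrR, ctrC, drop = FALSE] == "sunlit_leaf",
                  arr.ind = TRUE)
    offR <- ctrR[1] - 1L; offC <- ctrC[1] - 1L
    if (nrow(cand) == 0L) {
      # the central window is fully shaded/soil: widen to the whole plot,
      # preferring sunlit canopy, then any canopy; soil is never a sample
      cand <- which(mat == "sunlit_leaf", arr.ind = TRUE)
      if (nrow(cand) == 0L) cand <- which(mat != "soil", arr.ind = TRUE)
      if (nrow(cand) == 0L) cand <- which(mat == "soil", arr.ind = TRUE)
      offR <- 0L; offC <- 0L
    }
    pick <- cand[sample.int(nrow(cand), config$samplesPerPlot,
                            replace = nrow(cand) < config$samplesPerPlot), ,
                 drop = FALSE]
    sampleRows <- c(sampleRows, rIdx[1] - 1L + offR + pick[, 1])
    sampleCols <- c(sampleCols, cIdx[1] - 1L + offC + pick[, 2])
    samplePlot <- c(samplePlot, rep(p, config$samplesPerPlot))
  }

  # fill spectra (vectorised per plot and material)
  nb <- length(wl)
  soilBase <- soilSpectrum(wl, levelShift = stats::runif(1, -0.01, 0.01))
  flat <- matrix(0, R * C, nb)
  soilAll <- which(material == "soil" & alphaMat >= 1)
  flat[soilAll, ] <- outer(stats::runif(length(soilAll), 0.92, 1.08),
                           soilBase)
  for (p in seq_len(P)) {
    leafSun <- leafSpectrum(plotLnc[p], wl, lncRange = config$lncRange,
                            baseShift = plotBaseShift[p],
                            plateauShift = plotPlateauShift[p],
                            depthShift = plotDepthShift[p],
                            edgeShift = plotEdgeShift[p])
    inPlot <- plotId == p
    sun <- which(inPlot & material == "sunlit_leaf" & alphaMat >= 1)
    if (length(sun))
      flat[sun, ] <- outer(brightness[sun], leafSun)
    sh <- which(inPlot & material == "shaded_leaf")
    if (length(sh)) {
      sShade <- 1 / (1 + exp(-(wl - plotShadeEdge[p]) / 10))
      flat[sh, ] <- outer(brightness[sh] * shadeF[sh],
                          leafSun * (1 - plotNirExtra[p] * sShade))
    }
    mx <- which(inPlot & alphaMat < 1)  # boundary mixtures (either label)
    if (length(mx))
      flat[mx, ] <- outer(alphaMat[mx] * brightness[mx], leafSun) +
        outer(1 - alphaMat[mx], soilBase)
  }
  flat <- flat + matrix(stats::rnorm(length(flat), sd = config$noiseSd),
                        nrow(flat), nb)
  flat[flat < 5e-4] <- 5e-4
  arr <- array(flat, c(R, C, nb))

  samples <- data.frame(
    sample_id = sprintf("P%02d_S%d", samplePlot,
                        stats::ave(samplePlot, samplePlot, FUN = seq_along)),
    row = sampleRows, col = sampleCols,
    lnc = pmax(0.1, plotLnc[samplePlot] + stats::rnorm(length(samplePlot),
                                                       sd = 1.5)),
    plot = samplePlot, stringsAsFactors = FALSE)

  cube <- SpectralCube(arr, wl,
                       originNote = sprintf("synthetic scene (seed %d)",
                                            config$seed))
  list(cube = cube,
       truth = list(material = material, plotId = plotId,
                    plotLnc = plotLnc, samples = samples))
}
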