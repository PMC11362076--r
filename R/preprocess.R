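#' Pretreatment specification
#'
#' Describes one of the four per-spectrum noise pretreatments applied along
#' the wavelength axis: \code{OS} (original spectra, identity), \code{GF}
#' (Gaussian filter), \code{SG} (Savitzky-Golay smoothing) or \code{GFSG}
#' (Gaussian filter followed by Savitzky-Golay, in that order).
#'
#' Defaults (instrument sampling is typically finer than its optical
#' resolution, so mild smoothing below the resolution is safe):
#' \code{gfSigmaBands = 2} (about 4.4 nm on a 2.2 nm grid),
#' \code{sgWindow = 11}, \code{sgPolyorder = 2}.
#'
#' @param method one of "OS", "GF", "SG", "GFSG".
#' @param gfSigmaBands Gaussian standard deviation in band units (> 0).
#' @param sgWindow odd Savitzky-Golay window length (>= 3).
#' @param sgPolyorder polynomial order (0 <= order < window).
#' @return A list of class \code{"PreprocessSpec"}.
#' @export
preprocessSpec <- function(method = c("OS", "GF", "SG", "GFSG"),
                           gfSigmaBands = 2, sgWindow = 11L,
                           sgPolyorder = 2L) {
  method <- match.arg(toupper(method[1]), c("OS", "GF", "SG", "GFSG"))
  sgWindow <- as.integer(sgWindow); sgPolyorder <- as.integer(sgPolyorder)
  if (method %in% c("GF", "GFSG") && gfSigmaBands <= 0)
    stop("gfSigmaBands must be > 0")
  if (method %in% c("SG", "GFSG")) {
    if (sgWindow < 3L || sgWindow %% 2L == 0L)
      stop("sgWindow must be odd and >= 3")
    if (sgPolyorder < 0L || sgPolyorder >= sgWindow)
      stop("sgPolyorder must satisfy 0 <= order < window")
  }
  structure(list(method = method, gfSigmaBands = gfSigmaBands,
                 sgWindow = sgWindow, sgPolyorder = sgPolyorder),
            class = "PreprocessSpec")
}

# Discrete Gaussian kernel, truncated at 4 sigma, normalised to unit sum.
.gaussianKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n band-smoothing matrix for Gaussian convolution with reflect boundary
# (scipy-style: d c b a | a b c d | d c b a).
.gaussianMatrix <- function(n, sigma) {
  k <- .gaussianKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  # reflect index: map raw index to 1..n
  reflect <- function(i) {
    # reflect about the edges until inside [1, n]
    while (any(i < 1L | i > n)) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
    }
    i
  }
  G <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    w <- k[o + r + 1L]
    src <- reflect(seq_len(n) + o)
    G[cbind(seq_len(n), src)] <- G[cbind(seq_len(n), src)] + w
  }
  G
}

# n x n Savitzky-Golay smoothing matrix. Interior rows are the classical SG
# convolution coefficients; rows within half a window of either edge use a
# least-squares polynomial fit on the truncated window, evaluated at the
# output position. Falls back to a lower order when a truncated window has
# too few points.
.sgMatrix <- function(n, window, polyorder) {
  if (window > n) stop("sgWindow (", window, ") exceeds spectrum length (", n, ")")
  h <- (window - 1L) %/% 2L
  rowFor <- function(offsets, p) {
    X <- outer(offsets, 0:p, `^`)
    drop(solve(crossprod(X), t(X))[1L, ])
  }
  interior <- rowFor(seq(-h, h), polyorder)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      S[i, lo:hi] <- interior
    } else {
      p <- min(polyorder, hi - lo)
      S[i, lo:hi] <- rowFor((lo:hi) - i, p)
    }
  }
  S
}

#' Gaussian-filter a single spectrum
#'
#' 1-D Gaussian convolution along the wavelength axis with reflect boundary
#' handling; output length equals input length and a constant spectrum is
#' preserved (unit DC gain).
#'
#' @param spectrum numeric reflectance vector (length >= 3, finite).
#' @param sigma Gaussian standard deviation in band units (> 0).
#' @return Smoothed numeric vector.
#' @export
gaussianFilterSpectrum <- function(spectrum, sigma = 2) {
  if (any(!is.finite(spectrum))) stop("spectrum contains non-finite values")
  if (length(spectrum) < 3L) stop("spectrum length must be >= 3")
  if (sigma <= 0) stop("sigma must be > 0")
  drop(.gaussianMatrix(length(spectrum), sigma) %*% spectrum)
}

#' Savitzky-Golay smooth a single spectrum
#'
#' Local least-squares polynomial fit in a sliding window (convolutional
#' smoothing): signal shape and width are preserved while high-frequency
#' noise is removed. Boundaries use a polynomial fit on the truncated window.
#' A polynomial of degree <= \code{polyorder} is reproduced exactly.
#'
#' @param spectrum numeric reflectance vector.
#' @param window odd window length (>= 3, <= length of spectrum).
#' @param polyorder polynomial order (< window).
#' @return Smoothed numeric vector.
#' @export
sgSmoothSpectrum <- function(spectrum, window = 11L, polyorder = 2L) {
  if (any(!is.finite(spectrum))) stop("spectrum contains non-finite values")
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must satisfy 0 <= order < window")
  drop(.sgMatrix(length(spectrum), window, polyorder) %*% spectrum)
}

# Combined band-axis smoothing matrix for a PreprocessSpec (identity for OS).
.preprocessMatrix <- function(nbands, spec) {
  switch(spec$method,
    OS   = diag(nbands),
    GF   = .gaussianMatrix(nbands, spec$gfSigmaBands),
    SG   = .sgMatrix(nbands, spec$sgWindow, spec$sgPolyorder),
    GFSG = .sgMatrix(nbands, spec$sgWindow, spec$sgPolyorder) %*%
           .gaussianMatrix(nbands, spec$gfSigmaBands)
  )
}

#' Apply a pretreatment to one spectrum
#'
#' @param spectrum numeric reflectance vector.
#' @param spec a [preprocessSpec()].
#' @return Pretreated numeric vector.
#' @export
preprocessSpectrum <- function(spectrum, spec) {
  stopifnot(inherits(spec, "PreprocessSpec"))
  if (spec$method == "OS") return(spectrum)
  if (any(!is.finite(spectrum))) stop("spectrum contains non-finite values")
  drop(.preprocessMatrix(length(spectrum), spec) %*% spectrum)
}

#' Apply a pretreatment to every pixel spectrum of a cube
#'
#' Each pixel's spectrum is transformed independently along the wavelength
#' axis; spatial neighbours never mix. \code{GFSG} applies the Gaussian
#' filter first and Savitzky-Golay second; \code{OS} returns the cube
#' unchanged.
#'
#' @param cube a [SpectralCube-class].
#' @param spec a [preprocessSpec()].
#' @return A [SpectralCube-class] of identical dimensions.
#' @export
preprocessCube <- function(cube, spec) {
  stopifnot(is(cube, "SpectralCube"), inherits(spec, "PreprocessSpec"))
  if (spec$method == "OS") return(cube)
  arr <- reflectance(cube)
  d <- dim(arr)
  M <- .preprocessMatrix(d[3], spec)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])  # pixels x bands
  out <- array(flat %*% t(M), d)
  new("SpectralCube", reflectance = out, wavelengths = wavelengths(cube),
      originNote = originNote(cube), clipped = isClipped(cube))
}
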