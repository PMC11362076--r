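# Shared fixtures and independent oracles. Everything here is generated in
# code (no binary fixtures) and intentionally avoids reusing the package's
# own lookup/formula machinery where it serves as an oracle.

# The default instrument grid: 400-1000 nm at 2.2 nm sampling (273 bands).
defaultWl <- function() seq(400, by = 2.2, length.out = 273L)

# Independent nearest-band lookup (deliberately not bandIndex()).
oracleBand <- function(wl, nm) which.min(abs(wl - nm))

# Independently coded versions of the 20 index formulas, written longhand.
oracleIndices <- function(sp, wl) {
  v <- function(nm) sp[oracleBand(wl, nm)]
  c(ZMI     = v(750) / v(710),
    VOG1    = v(740) / v(720),
    GRVI    = v(800) / v(550),
    RVI     = v(800) / v(700),
    RG      = v(670) / v(550),
    MACI    = v(800) / v(550),
    RECI    = v(750) / v(550) - 1,
    GMI     = v(750) / v(720) - 1,
    GNDVI   = (v(780) - v(550)) / (v(780) + v(550)),
    NDVI    = (v(810) - v(560)) / (v(810) + v(560)),
    IPVI    = v(800) / (v(800) + v(670)),
    MTCI    = (v(754) - v(709)) / (v(709) - v(681)),
    SIPI    = (v(800) - v(450)) / (v(800) + v(450)),
    mSR705  = (v(750) - v(445)) / (v(705) + v(445)),
    NDVI801 = (v(801) - v(550)) / (v(801) + v(550)),
    RENDVI  = (v(750) - v(705)) / (v(750) + v(705)),
    mND705  = (v(750) - v(705)) / (v(750) + v(705) - 2 * v(445)),
    NPQI    = (v(415) - v(435)) / (v(415) + v(435)),
    HNDVI   = (v(827) - v(668)) / (v(827) + v(668)),
    SAVI    = 1.5 * (v(800) - v(670)) / (v(800) - v(670) + 0.5))
}

# Small random cube on an arbitrary wavelength grid.
randomCube <- function(rows, cols, wl, seed = 1L, lo = 0.05, hi = 0.9) {
  set.seed(seed)
  SpectralCube(array(runif(rows * cols * length(wl), lo, hi),
                     c(rows, cols, length(wl))), wl)
}

# Single-band "green image" cube for classifier tests.
greenCube <- function(values, rows, cols) {
  SpectralCube(array(values, c(rows, cols, 1L)), 550)
}

# A mask selecting every pixel (the criterion-6 all-pixel baseline).
allTrueMask <- function(nrowPx, ncolPx) {
  new("VegetationMask", mask = matrix(TRUE, nrowPx, ncolPx),
      methodNote = "all pixels")
}

# Brute-force level assignment: scan the edges directly; last bin closed on
# the right, values outside clamped into the extreme bins.
oracleAssign <- function(values, edges) {
  n <- length(edges) - 1L
  vapply(values, function(v) {
    if (v < edges[1]) return(0L)
    if (v >= edges[n + 1L]) return(n - 1L)
    for (lab in 0:(n - 1L)) {
      if (v >= edges[lab + 1L] && v < edges[lab + 2L]) return(lab)
    }
    n - 1L
  }, integer(1))
}
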