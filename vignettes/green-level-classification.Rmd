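---
title: "Green-band level classification against soil and leaf-shadow interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Green-band level classification against soil and leaf-shadow interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyLevels)
```

## The problem

A nadir-viewing hyperspectral camera over a row crop sees three materials:
sunlit leaves, leaves shaded by the canopy itself, and soil (pure or mixed
into canopy-boundary pixels). Leaf nitrogen content (LNC) is estimated from
vegetation indices (VIs) computed on the mean spectrum of a sampling
region of interest (ROI, 30 × 30 pixels here), and both contaminants bias
that mean: shade multiplies the spectrum by a factor well below one *and*
changes its spectral shape (shade light is sky light plus light transmitted
through leaves, so it is depleted at long wavelengths in a canopy-dependent
way), while soil adds a bright, red-edge-free ramp. The bias varies from
plot to plot with canopy closure and illumination, so it acts as noise on
the VI–LNC relationship rather than a fixable offset.

## The method

All steps are unsupervised and per scene:

1. **Vegetation mask.** Pixel spectra are clustered with k-means (k = 3 by
   default; soil, shaded and sunlit canopy separate naturally). Seeding is
   deterministic: initial centers are the pixels at evenly spaced quantiles
   of the per-pixel NIR(800)/red(670) ratio, so the mask does not depend on
   a random start. Clusters whose mean NIR/red ratio is at least 2 are
   vegetation.
2. **Stage 1.** The green-band (550 nm) reflectance of the masked pixels is
   divided into 10 equal-width levels spanning the observed min–max (the
   last bin closed on the right, the others half-open). Shaded pixels fall
   into the low levels, soil-edge mixtures into the high levels; levels 4
   and 5 are kept as sunlit-canopy candidates.
3. **Stage 2.** A fresh 10-level scheme is fitted on the kept pixels'
   narrowed green range and they are re-binned; levels 3–5 are retained for
   analysis. The second pass refines the coarse stage-1 cut: residual dark
   (shade-touched) and bright (mixture-touched) pixels move to the extreme
   stage-2 levels and are dropped.
4. **Indices and screening.** For each ground sample, the mean spectrum of
   the retained pixels in its ROI is (optionally) smoothed and evaluated
   under 20 standard VIs; each VI is screened against LNC by Pearson
   correlation (t-based p-value), and indices with p < 0.05 and |r| ≥ 0.2
   are "sensitive".
5. **Regression.** Sensitive VI columns are combined per class, joined by
   sample, standardised, split 70/30, and fed to MLR, PCR, PLSR (NIPALS) or
   SVMR (RBF, grid-searched by internal cross-validation). Metrics (R²,
   RMSE, MAE) are reported on the held-out samples only.

```{r demo}
scene <- generateScene(sceneConfig(seed = 1))
mask <- vegetationMask(scene$cube)
maps <- cascadeClassify(scene$cube, mask)
tab <- buildViTable(scene$cube, maps$stage2, scene$truth$samples,
                    labels = 3:5)
head(correlateViLnc(list(tab)), 5)
```

## Numerical and design choices

- **Coordinates are 1-based** (row, column), matching R array indexing;
  sample tables on disk carry the same convention.
- **Even ROI sizes** (including the default 30 × 30) anchor the center at
  the upper-left pixel of the central 2 × 2 block: rows
  `row − (h−1)%/%2 … row + h%/%2`. Edge-overlapping ROIs are clipped, and
  the extracted cube carries a `clipped` flag.
- **Band lookup is nearest-center** with a default tolerance of one median
  sampling interval; ties break toward the lower wavelength. Index
  formulas therefore work on any grid that actually covers their bands.
- **Equal-width levels on the observed min–max** are the default because
  the method's physical reading ("dark = shade, bright = soil") is about
  absolute green intensity; quantile levels are available but would fix the
  per-level pixel share rather than the intensity cut points.
- **Smoothing order:** `buildViTable()` smooths the ROI *mean* spectrum
  once instead of smoothing every pixel. Both pretreatments are linear
  operators along the wavelength axis, so the two orders are numerically
  identical (tested to 1e-12) and the cheap one is used.
- **Savitzky–Golay boundaries** fit the polynomial on the truncated window
  (reducing the order if the window is shorter than `order + 1`) rather
  than padding; interior rows are the classical convolution coefficients —
  window 5, order 2 gives (−3, 12, 17, 12, −3)/35.
- **Gaussian filtering** uses a 4σ-truncated kernel with reflect boundary
  handling and exact unit DC gain.
- **Compact letter displays** are built from the Tukey HSD p-value matrix
  as maximal cliques of the non-significance graph, letters assigned in
  descending-mean order ("a" = highest mean).
- **Determinism:** every stochastic step (scene generation, splits, CV
  folds, feature subsetting) is driven by an explicit integer seed, and the
  pipeline manifest records md5 hashes so reruns can be verified
  byte-for-byte.

## What the simulator emulates — and what it does not

`generateScene()` is a *testing instrument*, not a radiative-transfer
model. It emulates the structure of a small fertilizer-gradient trial: 18
plots of 36 × 36 pixels, five applied-N levels assigned round-robin with
plot-level jitter, ~65 % canopy cover in spatially clumped patches, ~35 %
of canopy shaded (jittered per plot), soil–leaf mixtures on canopy
boundaries, six ground samples per plot (108 total) with LNC measured with
error.

The leaf model is analytic: a visible baseline with Gaussian pigment
absorption wells at 450 and 670 nm whose depth grows with LNC (so green
reflectance falls as LNC rises), a logistic red edge whose inflection
shifts from ~714 to ~724 nm with LNC (the classical chlorophyll red-edge
shift), and a NIR plateau that *decreases* with LNC — denser, high-N
canopies self-shade more at the top of the canopy, and this choice
reproduces the negative correlations of simple ratio indices (e.g.
NIR/green) with LNC that are observed in field data. Shade multiplies the
sunlit spectrum by a per-pixel factor in (0.2, 0.5) and additionally
attenuates long wavelengths through a logistic whose strength and
transition wavelength vary per plot — that is the mechanism by which shade
contaminates red-edge indices in a way a per-scene constant could not.
Plot-level nuisance terms (baseline, plateau, well depth, edge position)
are LNC-independent and cap the attainable correlations in a realistic
field regime instead of a deterministic laboratory one.

Not emulated: directional effects (BRDF), atmospheric or illumination
drift across the scene, row structure, water/protein absorption features
beyond 1000 nm, sensor smile/keystone, or spatially correlated sensor
noise. Conclusions about those must come from real data. The simulator's
job is narrower: it provides scenes where the true material of every pixel
and the true LNC of every sample are known, so the de-interference claim —
restricting to mid-green levels raises |r(VI, LNC)| and removes truth
contamination — is checkable, mechanically, in the test suite.

## Problem sizes

The default scene (108 × 216 × 273 ≈ 6.4 M values) generates in about two
seconds; a full pipeline run (mask, cascade, eight VI tables, screening,
two models) takes a few seconds more. The acceptance checks sweep 20 such
scenes. These sizes were chosen so that the whole suite runs on one CPU in
minutes while still being an order of magnitude larger than the windows
and plot structures under test.
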