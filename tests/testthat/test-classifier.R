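test_that("equal-width level schemes span the observed min-max evenly", {
  v <- c(0.12, 0.5, 0.34, 0.9, 0.77)
  sch <- fitLevelScheme(v, nLevels = 10)
  expect_equal(levelEdges(sch), seq(0.12, 0.9, length.out = 11))
  expect_identical(nLevels(sch), 10L)
  expect_error(fitLevelScheme(rep(0.3, 5)), "constant")
})

test_that("quantile schemes place edges at i/n quantiles", {
  set.seed(31)
  v <- runif(500)
  sch <- fitLevelScheme(v, nLevels = 4, mode = "quantile")
  expect_equal(levelEdges(sch),
               unname(quantile(v, seq(0, 1, 0.25), type = 7)))
  expect_error(fitLevelScheme(c(1, 2, 3), nLevels = 10, mode = "quantile"),
               "distinct")
})

test_that("level assignment matches a brute-force edge scan", {
  set.seed(32)
  g <- matrix(runif(400, 0.1, 0.8), 20, 20)
  cube <- greenCube(g, 20, 20)
  m <- matrix(TRUE, 20, 20)
  map <- classifyStage(cube, m, nLevels = 10)
  sch <- levelScheme(map)
  expect_identical(as.vector(labelMatrix(map)),
                   oracleAssign(as.vector(g), levelEdges(sch)))
  # the maximum lands in the top bin (last bin right-closed)
  expect_identical(labelMatrix(map)[which.max(g)], 9L)
  expect_identical(labelMatrix(map)[which.min(g)], 0L)
})

test_that("unselected pixels stay at -1 and empty masks error", {
  g <- matrix(runif(100), 10, 10)
  cube <- greenCube(g, 10, 10)
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  map <- classifyStage(cube, m)
  expect_true(all(labelMatrix(map)[!m] == -1L))
  expect_true(all(labelMatrix(map)[m] >= 0L))
  expect_error(classifyStage(cube, matrix(FALSE, 10, 10)), "empty mask")
})

test_that("the cascade refits on kept pixels and nests inside stage1Keep", {
  set.seed(33)
  g <- matrix(runif(2500, 0.05, 0.6), 50, 50)
  cube <- greenCube(g, 50, 50)
  mask <- new("VegetationMask", mask = matrix(TRUE, 50, 50),
              methodNote = "test")
  maps <- cascadeClassify(cube, mask, stage1Keep = c(4L, 5L))
  l1 <- labelMatrix(maps$stage1); l2 <- labelMatrix(maps$stage2)
  # nesting: stage-2 labels exist exactly where stage 1 kept the pixel
  expect_identical(l2 >= 0L, l1 %in% c(4L, 5L) & l1 >= 0L)
  # stage 2 refits on the narrowed green range of kept pixels
  kept <- g[l1 %in% c(4L, 5L)]
  expect_equal(levelEdges(levelScheme(maps$stage2)),
               seq(min(kept), max(kept), length.out = 11))
  expect_error(cascadeClassify(cube, mask, stage1Keep = integer(0)),
               "non-empty")
})

test_that("the vegetation mask separates canopy from soil on a toy scene", {
  wl <- c(550, 670, 800)
  arr <- array(0, c(20, 20, 3))
  veg <- matrix(FALSE, 20, 20); veg[, 1:10] <- TRUE
  set.seed(34)
  for (b in 1:3) {
    base <- c(0.08, 0.05, 0.5)[b]     # vegetation: dark red, bright NIR
    soil <- c(0.2, 0.25, 0.3)[b]      # soil: bright red, flat NIR
    arr[, , b] <- ifelse(veg, base, soil) + runif(400, 0, 0.01)
  }
  cube <- SpectralCube(arr, wl)
  mask <- vegetationMask(cube)
  expect_identical(maskMatrix(mask), veg)
  # deterministic: independent of the seed argument
  expect_identical(maskMatrix(vegetationMask(cube, seed = 99)),
                   maskMatrix(mask))
})

test_that("degenerate all-identical cubes yield an all-true mask + warning", {
  cube <- SpectralCube(array(0.3, c(5, 5, 3)), c(550, 670, 800))
  expect_warning(mask <- vegetationMask(cube), "identical")
  expect_true(all(maskMatrix(mask)))
})

test_that("pixel statistics report counts and percentages with a total row", {
  m <- matrix(c(rep(TRUE, 30), rep(FALSE, 70)), 10, 10)
  st <- classPixelStats(new("VegetationMask", mask = m, methodNote = "t"))
  expect_identical(st$label, c("vegetation", "other", "total"))
  expect_identical(st$pixels, c(30L, 70L, 100L))
  expect_equal(st$percent, c(30, 70, 100))

  g <- matrix(runif(100), 10, 10)
  map <- classifyStage(greenCube(g, 10, 10), matrix(TRUE, 10, 10))
  st2 <- classPixelStats(map)
  expect_identical(st2$pixels[st2$label == "total"], 100L)
  expect_equal(sum(st2$pixels[st2$label != "total"]), 100L)
})

test_that("class-restricted ROI means match hand computation or go NULL", {
  set.seed(35)
  wl <- c(550, 670, 800)
  cube <- randomCube(20, 20, wl, seed = 35)
  g <- reflectance(cube)[, , 1]
  map <- classifyStage(cube, matrix(TRUE, 20, 20), nLevels = 4)
  # even 6 x 6 window at (10, 10): rows 10 - 2 .. 10 + 3 = 8:13
  r <- roi(10, 10, 6, 6)
  lab <- labelMatrix(map)[8:13, 8:13]
  want <- 2L
  if (any(lab == want)) {
    sp <- classMeanSpectrum(cube, map, r, labels = want)
    sub <- reflectance(cube)[8:13, 8:13, , drop = FALSE]
    flat <- matrix(sub, 36, 3)
    expect_equal(sp, colMeans(flat[as.vector(lab == want), , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # a label that cannot occur: NULL with message, not an error
  expect_message(res <- classMeanSpectrum(cube, map, r, labels = 99L),
                 "no pixel")
  expect_null(res)
})
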