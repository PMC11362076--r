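test_that("prediction metrics satisfy their contracts", {
  obs <- c(30, 35, 40, 45)
  m <- evaluatePredictions(obs, obs)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  set.seed(61)
  for (i in 1:20) {
    p <- rnorm(50); o <- rnorm(50)
    mm <- evaluatePredictions(p, o)
    expect_gte(mm$rmse, mm$mae)
    # hand oracle
    expect_equal(mm$r2, 1 - sum((p - o)^2) / sum((o - mean(o))^2),
                 tolerance = 1e-12)
  }
  # worse-than-mean predictions go negative (unclamped)
  expect_lt(evaluatePredictions(rep(100, 4), obs)$r2, 0)
  expect_error(evaluatePredictions(1:3, 1:4), "equal length")
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  s1 <- splitSamples(100, 0.3, seed = 7)
  s2 <- splitSamples(100, 0.3, seed = 7)
  s3 <- splitSamples(100, 0.3, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_identical(sort(c(s1$train, s1$test)), 1:100)
  expect_identical(length(s1$test), 30L)
  expect_error(splitSamples(10, 1.2), "testFraction")
})

test_that("combineFeatures joins by id, standardises, names class.index", {
  tabA <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     lnc = c(30, 34, 38, 42),
                     NDVI = c(0.5, 0.6, 0.7, 0.8),
                     GRVI = c(2, 3, 4, 5), stringsAsFactors = FALSE)
  tabB <- tabA; tabB$NDVI <- tabB$NDVI + 0.05
  f <- combineFeatures(list(`2-4` = tabA, `2-5` = tabB),
                       list(`2-4` = c("NDVI", "GRVI"), `2-5` = "NDVI"))
  expect_identical(colnames(f$x), c("2-4.NDVI", "2-4.GRVI", "2-5.NDVI"))
  expect_equal(unname(colMeans(f$x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(f$x, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(f$y, tabA$lnc)
  # samples missing from one class are dropped by the join
  f2 <- combineFeatures(list(`2-4` = tabA, `2-5` = tabB[1:3, ]),
                        list(`2-4` = "NDVI", `2-5` = "NDVI"))
  expect_identical(nrow(f2$x), 3L)
})

test_that("random_subset mode draws a seeded column subset", {
  tab <- data.frame(sample_id = sprintf("s%d", 1:10), lnc = runif(10, 28, 46),
                    matrix(rnorm(40), 10, 4,
                           dimnames = list(NULL, c("a", "b", "c", "d"))),
                    stringsAsFactors = FALSE)
  f1 <- combineFeatures(list(k = tab), list(k = c("a", "b", "c", "d")),
                        mode = "random_subset", k = 2, seed = 3)
  f2 <- combineFeatures(list(k = tab), list(k = c("a", "b", "c", "d")),
                        mode = "random_subset", k = 2, seed = 3)
  expect_identical(colnames(f1$x), colnames(f2$x))
  expect_identical(ncol(f1$x), 2L)
})

# Deterministic noiseless features for the model contracts below.
.linearFeatures <- function(n = 80, p = 4, seed = 62) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("s%d", 1:n),
                                                  paste0("f", 1:p)))
  y <- drop(x %*% c(3, -2, 1, 0.5)) + 35
  list(x = scale(x)[, ], y = y)
}

test_that("MLR recovers an exact linear relationship", {
  f <- .linearFeatures()
  rep_ <- fitPredict(f, "MLR", seed = 1)
  expect_equal(rep_$r2, 1, tolerance = 1e-8)
  expect_lt(rep_$rmse, 1e-6)
  expect_identical(nrow(rep_$predictions), 24L)  # 0.3 * 80
})

test_that("MLR refuses p >= n and points at the latent-variable methods", {
  set.seed(63)
  f <- list(x = matrix(rnorm(20 * 30), 20, 30), y = rnorm(20))
  expect_error(fitPredict(f, "MLR", seed = 1, folds = 2), "PCR or PLSR")
})

test_that("PCR and PLSR fit near-perfectly on noiseless linear data", {
  f <- .linearFeatures()
  for (m in c("PCR", "PLSR")) {
    rep_ <- fitPredict(f, m, seed = 1)
    expect_gt(rep_$r2, 0.999)
    expect_true(rep_$hyperparameters$ncomp >= 1)
  }
})

test_that("full-rank NIPALS coefficients equal ordinary least squares", {
  set.seed(64)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(50, sd = 0.1) + 10
  b <- canopyLevels:::.nipalsPls(X, y, 4L)(4L)
  ls <- lm(y ~ X)
  expect_equal(b$coef, unname(coef(ls)[-1]), tolerance = 1e-8)
  expect_equal(b$intercept, unname(coef(ls)[1]), tolerance = 1e-8)
})

test_that("SVMR returns finite seeded-reproducible metrics", {
  f <- .linearFeatures(seed = 65)
  r1 <- fitPredict(f, "SVMR", seed = 2)
  r2 <- fitPredict(f, "SVMR", seed = 2)
  expect_identical(r1$r2, r2$r2)
  expect_true(is.finite(r1$r2) && is.finite(r1$rmse) && is.finite(r1$mae))
  expect_gt(r1$r2, 0.8)
  expect_named(r1$hyperparameters, c("cost", "gamma", "epsilon"))
})

test_that("a supplied split is honoured across methods", {
  f <- .linearFeatures(seed = 66)
  sp <- splitSamples(80, 0.3, seed = 9)
  rA <- fitPredict(f, "MLR", seed = 1, split = sp)
  rB <- fitPredict(f, "PLSR", seed = 1, split = sp)
  expect_identical(rA$predictions$sample_id, rB$predictions$sample_id)
  expect_identical(rA$predictions$observed, rB$predictions$observed)
})
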