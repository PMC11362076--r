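test_that("pearsonR matches cor.test to high precision", {
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    pr <- pearsonR(x, y)
    ct <- cor.test(x, y)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
    expect_identical(pr$n, 30L)
  }
  expect_error(pearsonR(1:5, 1:4), "equal length")
  expect_error(pearsonR(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearsonR(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("NA pairs are dropped pairwise and perfect correlation gives p = 0", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, 8, 10)
  pr <- pearsonR(x, y)
  expect_identical(pr$n, 4L)
  expect_equal(pr$r, 1)
  expect_equal(pr$p, 0)
})

test_that("correlateViLnc produces an |r|-ordered long report", {
  set.seed(52)
  lnc <- runif(40, 28, 46)
  tab <- data.frame(sample_id = sprintf("s%02d", 1:40), lnc = lnc,
                    strong = lnc * -2 + rnorm(40, sd = 1),
                    weak = rnorm(40),
                    flat = rep(1, 40),            # skipped: zero variance
                    stringsAsFactors = FALSE)
  attr(tab, "classLabel") <- "2-4"; attr(tab, "pretreat") <- "GFSG"
  rep_ <- correlateViLnc(tab)
  expect_identical(rep_$index, c("strong", "weak"))  # ordered by |r|
  expect_identical(rep_$class[1], "2-4")
  expect_identical(rep_$method[1], "GFSG")
  expect_true(abs(rep_$r[1]) > abs(rep_$r[2]))
  expect_identical(rep_$stars[1], "**")
  ct <- cor.test(tab$strong, lnc)
  expect_equal(rep_$r[1], unname(ct$estimate), tolerance = 1e-12)
})

test_that("standard errors equal sd/sqrt(n) per index", {
  set.seed(53)
  tab <- data.frame(sample_id = letters[1:10], lnc = runif(10, 28, 46),
                    a = rnorm(10), b = runif(10), stringsAsFactors = FALSE)
  se <- viStandardError(tab)
  expect_equal(se[["a"]], sd(tab$a) / sqrt(10), tolerance = 1e-12)
  expect_equal(se[["b"]], sd(tab$b) / sqrt(10), tolerance = 1e-12)
})

test_that("anovaLetters assigns descending-mean letters; cld cross-check", {
  set.seed(54)
  g <- factor(rep(c("high", "mid", "low"), each = 12))
  v <- c(rnorm(12, 10, 0.3), rnorm(12, 5, 0.3), rnorm(12, 0, 0.3))
  out <- anovaLetters(v, g)
  expect_identical(out$group, c("high", "mid", "low"))  # sorted by mean
  expect_identical(out$letters, c("a", "b", "c"))       # all distinct

  # overlapping design: compare sharing structure against multcomp::cld
  v2 <- c(rnorm(12, 1.0, 0.8), rnorm(12, 0.7, 0.8), rnorm(12, 0, 0.8))
  out2 <- anovaLetters(v2, g)
  fit <- aov(v2 ~ g, data = data.frame(v2 = v2, g = g))
  cl <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")),
                      decreasing = TRUE)
  oracle <- cl$mcletters$Letters
  share <- function(lets, a, b)
    length(intersect(strsplit(lets[a], "")[[1]],
                     strsplit(lets[b], "")[[1]])) > 0
  lets <- setNames(out2$letters, out2$group)
  for (a in levels(g)) for (b in levels(g)) if (a < b)
    expect_identical(share(lets, a, b), share(oracle, a, b),
                     label = paste("sharing", a, b))
})

test_that("anovaLetters handles identical groups and validates input", {
  g <- rep(c("a", "b"), each = 5)
  out <- anovaLetters(rep(3, 10), g)
  expect_identical(out$letters, c("a", "a"))   # equal means share a letter
  expect_error(anovaLetters(rnorm(5), rep("x", 5)), "at least 2 groups")
  expect_error(anovaLetters(rnorm(3), c("a", "a", "b")), "singleton")
})

test_that("sensitive selection enforces both thresholds per class", {
  rep_ <- data.frame(
    class = c("2-3", "2-3", "2-3", "2-4"),
    method = "GFSG",
    index = c("big", "insig", "tiny", "big"),
    r = c(0.8, 0.9, 0.1, -0.5),
    p = c(0.001, 0.2, 0.001, 0.01),
    stars = "", n = 30L, stringsAsFactors = FALSE)
  sens <- selectSensitive(rep_, alpha = 0.05, minAbsR = 0.2)
  expect_identical(sens[["2-3"]], "big")      # insig fails p, tiny fails |r|
  expect_identical(sens[["2-4"]], "big")      # negative r counts by magnitude
  expect_identical(attr(sens, "counts"), c(`2-3` = 1L, `2-4` = 1L))
})
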