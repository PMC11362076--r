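test_that("ENVI float64 round trip is value-exact for every interleave", {
  wl <- c(500, 550, 600, 650)
  cube <- randomCube(5, 7, wl, seed = 11)
  for (il in c("bsq", "bil", "bip")) {
    hdr <- file.path(tempdir(), paste0("rt_", il, ".hdr"))
    writeEnviCube(cube, hdr, interleave = il, dataType = 5L)
    back <- readEnviCube(hdr)
    expect_identical(reflectance(back), reflectance(cube))
    expect_equal(wavelengths(back), wl)
  }
})

test_that("ENVI float32 round trip is accurate to single precision", {
  cube <- randomCube(4, 4, c(500, 600), seed = 3)
  hdr <- file.path(tempdir(), "rt_f32.hdr")
  writeEnviCube(cube, hdr, dataType = 4L)
  back <- readEnviCube(hdr)
  expect_equal(reflectance(back), reflectance(cube), tolerance = 1e-6)
})

test_that("reflectance scale factor divides integer counts into fractions", {
  # hand-written header + int16 binary, scale factor 10000
  stem <- file.path(tempdir(), "scaled")
  counts <- matrix(c(1234L, 5000L, 9999L, 42L, 777L, 3000L), nrow = 1)
  con <- file(paste0(stem, ".dat"), "wb")
  # bsq, 1 line x 3 samples x 2 bands
  writeBin(as.integer(c(counts[1, 1:3], counts[1, 4:6])), con,
           size = 2L, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 3", "lines = 1", "bands = 2",
               "header offset = 0", "data type = 2", "interleave = bsq",
               "byte order = 0", "reflectance scale factor = 10000",
               "wavelength = { 550, 800 }"),
             paste0(stem, ".hdr"))
  cube <- readEnviCube(paste0(stem, ".hdr"))
  expect_equal(reflectance(cube)[1, , 1], c(1234, 5000, 9999) / 10000)
  expect_equal(reflectance(cube)[1, , 2], c(42, 777, 3000) / 10000)
})

test_that("ENVI reader rejects missing wavelengths and size mismatches", {
  cube <- randomCube(3, 3, c(500, 600), seed = 5)
  hdr <- file.path(tempdir(), "bad.hdr")
  writeEnviCube(cube, hdr)
  txt <- readLines(hdr)
  writeLines(txt[!grepl("^wavelength =", txt)], hdr)
  expect_error(readEnviCube(hdr), "wavelength")

  hdr2 <- file.path(tempdir(), "bad2.hdr")
  writeEnviCube(cube, hdr2)
  txt <- readLines(hdr2)
  writeLines(sub("lines = 3", "lines = 4", txt, fixed = TRUE), hdr2)
  expect_error(readEnviCube(hdr2), "does not match")
})

test_that("multiline wavelength lists parse", {
  cube <- randomCube(2, 2, c(500, 600, 700), seed = 6)
  hdr <- file.path(tempdir(), "ml.hdr")
  writeEnviCube(cube, hdr)
  txt <- readLines(hdr)
  i <- grep("^wavelength =", txt)
  txt[i] <- "wavelength = { 500,"
  writeLines(c(txt[seq_len(i)], "  600,", "  700 }"), hdr)
  expect_equal(wavelengths(readEnviCube(hdr)), c(500, 600, 700))
})

test_that("bandIndex finds nearest band, breaks ties low, enforces tolerance", {
  wl <- defaultWl()
  expect_identical(bandIndex(wl, 550), oracleBand(wl, 550))
  expect_identical(bandIndex(wl, 800), oracleBand(wl, 800))
  # exact tie: midpoint between two centers goes to the lower wavelength
  expect_identical(bandIndex(c(548.9, 551.1), 550), 1L)
  # out of tolerance: error names the nearest available band
  expect_error(bandIndex(c(500, 502.2), 900), "501|502", ignore.case = TRUE)
  expect_error(bandIndex(wl, 550, tolNm = 0), "tolNm")
})

test_that("ROI windows have the documented extent for odd and even sizes", {
  cube <- randomCube(100, 100, c(500, 550), seed = 7)
  # even 30 x 30: rows r-14 .. r+15
  sub <- extractRoi(cube, roi(50, 50, 30, 30))
  expect_identical(spatialDims(sub), c(30L, 30L))
  expect_identical(reflectance(sub)[1, 1, 1], reflectance(cube)[36, 36, 1])
  expect_identical(reflectance(sub)[30, 30, 1], reflectance(cube)[65, 65, 1])
  expect_false(isClipped(sub))
  # odd 5 x 5 symmetric
  sub5 <- extractRoi(cube, roi(50, 50, 5, 5))
  expect_identical(reflectance(sub5),
                   reflectance(cube)[48:52, 48:52, , drop = FALSE])
})

test_that("edge-overlapping ROIs clip and flag; outside centers error", {
  cube <- randomCube(40, 40, c(500, 550), seed = 8)
  sub <- extractRoi(cube, roi(2, 2, 30, 30))
  expect_true(isClipped(sub))
  expect_identical(spatialDims(sub), c(17L, 17L))  # rows 1..17, cols 1..17
  expect_error(extractRoi(cube, roi(41, 5)), "outside")
})

test_that("sample tables validate columns, ids and LNC with row numbers", {
  p <- file.path(tempdir(), "samp.csv")
  write.csv(data.frame(sample_id = c("a", "b"), row = 1:2, col = 3:4,
                       lnc = c(30.5, 42)), p, row.names = FALSE)
  tab <- readSampleTable(p)
  expect_identical(tab$sample_id, c("a", "b"))
  expect_identical(tab$row, 1:2)
  expect_equal(tab$lnc, c(30.5, 42))

  write.csv(data.frame(sample_id = c("a", "a"), row = 1:2, col = 3:4,
                       lnc = c(30, 40)), p, row.names = FALSE)
  expect_error(readSampleTable(p), "duplicate sample_id.*2")

  write.csv(data.frame(sample_id = c("a", "b"), row = 1:2, col = 3:4,
                       lnc = c(30, -1)), p, row.names = FALSE)
  expect_error(readSampleTable(p), "lnc at row.*2")

  write.csv(data.frame(sample_id = "a", row = 1, col = 2), p,
            row.names = FALSE)
  expect_error(readSampleTable(p), "missing column.*lnc")
})

test_that("class maps export as int32 rasters", {
  lab <- matrix(c(-1L, 0L, 4L, 9L, 2L, -1L), 2, 3)
  map <- new("PixelClassMap", labels = lab,
             scheme = fitLevelScheme(runif(50), 10),
             stage = 1L, labelPrefix = "1-")
  hdr <- file.path(tempdir(), "cls.hdr")
  writeEnviClassMap(map, hdr)
  con <- file(paste0(sub("\\.hdr$", "", hdr), ".dat"), "rb")
  vals <- readBin(con, "integer", 6, size = 4L, endian = "little")
  close(con)
  expect_identical(matrix(vals, 2, 3, byrow = TRUE), lab)
})
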