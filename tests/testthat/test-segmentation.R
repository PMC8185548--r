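test_that("global threshold is mean + k * population SD", {
  img <- ChannelImage(matrix(c(rep(0, 8), 10), 3, 3))
  # eight zeros and one ten: mean 10/9, population SD sqrt(E[x^2] - mean^2)
  expect_equal(globalThreshold(img, 2), 10 / 9 + 2 * sqrt(100 / 9 - 100 / 81))
  expect_equal(globalThreshold(img, 2), 7.3965, tolerance = 1e-4)
  expect_identical(sum(pixels(img) > globalThreshold(img, 2)), 1L)
  # k = 0 reduces to the mean; constant image gives an empty mask
  expect_equal(globalThreshold(img, 0), mean(pixels(img)))
  const <- ChannelImage(matrix(5, 4, 4))
  expect_equal(globalThreshold(const, 2), 5)
  expect_false(any(pixels(const) > globalThreshold(const, 2)))
})

test_that("threshold is translation/rotation invariant and affine in intensity", {
  set.seed(31)
  m <- matrix(rexp(20 * 16, 1 / 50), 20, 16)
  thr <- globalThreshold(ChannelImage(m))
  shifted <- m[c(6:20, 1:5), ]           # cyclic translation
  expect_equal(globalThreshold(ChannelImage(shifted)), thr)
  expect_equal(globalThreshold(ChannelImage(t(m)[ncol(m):1, ])), thr)  # 90 deg
  a <- 3.2; b <- 17
  expect_equal(globalThreshold(ChannelImage(a * m + b)), a * thr + b)
})

test_that("disjoint in-range disks are counted; undersized blobs filtered", {
  m <- matrix(0, 96, 96)
  d1 <- (row(m) - 30)^2 + (col(m) - 30)^2 <= 8^2
  d2 <- (row(m) - 65)^2 + (col(m) - 65)^2 <= 8^2
  m[d1 | d2] <- 100
  lm <- segmentNuclei(ChannelImage(m), segmentationParams(
    minAreaPx = 50, maxAreaPx = 500, minSeedDistPx = 6))
  expect_identical(nCells(lm), 2L)
  # area below the lower bound: rejected
  tiny <- matrix(0, 64, 64)
  tiny[(row(tiny) - 32)^2 + (col(tiny) - 32)^2 <= 3^2] <- 100
  lm2 <- segmentNuclei(ChannelImage(tiny), segmentationParams(
    minAreaPx = 100, maxAreaPx = 1000, minSeedDistPx = 4))
  expect_identical(nCells(lm2), 0L)
})

test_that("an image with nothing above threshold yields an empty LabelMap", {
  lm <- segmentNuclei(ChannelImage(matrix(7, 64, 64)))
  expect_identical(nCells(lm), 0L)
  expect_true(all(labelMatrix(lm) == 0L))
})

test_that("touching nuclei are split by the seeded watershed", {
  sc <- simulatePLAScene(seed = 21, nNuclei = 0, nTouchingPairs = 1)
  lm <- segmentNuclei(sc$hoechst)
  expect_identical(nCells(lm), 2L)
})

test_that("segmentation is deterministic and labels are raster-ordered,
           8-connected and inside the threshold mask", {
  sc <- simulatePLAScene(seed = 8, nNuclei = 5, nTouchingPairs = 1)
  lm1 <- segmentNuclei(sc$hoechst)
  lm2 <- segmentNuclei(sc$hoechst)
  expect_identical(labelMatrix(lm1), labelMatrix(lm2))
  mask <- pixels(sc$hoechst) > globalThreshold(sc$hoechst)
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  l <- labelMatrix(lm1)
  expect_true(all(mask[l > 0]))
  # each labelled region is one 8-connected component
  for (k in seq_len(nCells(lm1))) {
    comp <- cellquant:::label8(l == k)
    expect_identical(max(comp), 1L)
  }
  # raster order of top-left pixels is increasing in label
  nc <- ncol(l)
  key <- vapply(seq_len(nCells(lm1)), function(k) {
    idx <- which(l == k)
    r <- (idx - 1) %% nrow(l) + 1; c <- (idx - 1) %/% nrow(l) + 1
    min((r - 1) * nc + (c - 1))
  }, numeric(1))
  expect_identical(key, sort(key))
})

test_that("nuclear counts are recovered on non-touching scenes", {
  hits <- 0L
  for (s in 1:20) {
    sc <- simulatePLAScene(seed = 300 + s, nNuclei = 6)
    if (nCells(segmentNuclei(sc$hoechst)) == 6L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
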