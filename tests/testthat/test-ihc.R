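matchCentroids <- function(centroids, colors) {
  # map each generating colour to its nearest centroid index
  apply(colors, 1L, function(col) {
    which.min(colSums((t(centroids) - col)^2))
  })
}

test_that("noiseless four-colour tiles are recovered exactly", {
  tile <- simulateIHCScene(seed = 21, imageShape = c(64, 64),
                           positiveFraction = 0.3, colorNoiseSd = 0)
  cl <- clusterPixels(tile$rgb, K = 4, seed = 21)
  mp <- matchCentroids(cl$centroids, tile$truth@classColors)
  expect_equal(cl$centroids[mp, ], unname(tile$truth@classColors),
               tolerance = 1e-12)
  relabel <- integer(4); relabel[mp] <- 1:4
  expect_identical(matrix(relabel[cl$classLabels], 64, 64),
                   tile$truth@classMap)
})

test_that("K = 1 degenerates to the mean colour", {
  tile <- simulateIHCScene(seed = 22, imageShape = c(32, 32))
  cl <- clusterPixels(tile$rgb, K = 1, seed = 1)
  want <- c(mean(tile$rgb[, , 1]), mean(tile$rgb[, , 2]),
            mean(tile$rgb[, , 3]))
  expect_equal(as.numeric(cl$centroids), want)
  expect_true(all(cl$classLabels == 1L))
})

test_that("fewer distinct colours than K is an error", {
  flat <- array(rep(c(10, 20, 30), each = 16), c(4, 4, 3))
  expect_error(clusterPixels(flat, K = 4, seed = 1), "distinct colours")
})

test_that("class identification: white is background, nearest-to-DAB is positive", {
  cen <- rbind(c(255, 255, 255), c(120, 80, 45),
               c(60, 60, 150), c(220, 180, 190))
  id <- identifyClasses(cen)
  expect_identical(id$backgroundClass, 1L)
  expect_identical(id$positiveClass, 2L)
  # re-pointing the reference picks out the blue centroid instead
  idBlue <- identifyClasses(cen, referencePositiveRGB = c(60, 60, 150))
  expect_identical(idBlue$positiveClass, 3L)
})

test_that("negative fraction handles the boundary compositions", {
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2)   # classes: 1 positive, 2 background
  expect_equal(negativePixelFraction(lab, 1L, 2L), 0)
  expect_equal(negativePixelFraction(lab, 3L, 2L), 1)
  expect_error(negativePixelFraction(matrix(2L, 2, 2), 1L, 2L), "tissue")
})

test_that("noiseless construction yields the complementary fraction", {
  tile <- simulateIHCScene(seed = 23, imageShape = c(64, 64),
                           positiveFraction = 0.3, colorNoiseSd = 0)
  cls <- classifyIHC(tile$rgb, seed = 23)
  expect_equal(negativeFraction(cls),
               1 - tile$truth@positiveFractionTruth, tolerance = 1e-12)
})

test_that("noisy tiles: >= 99% label agreement and accurate fractions", {
  tile <- simulateIHCScene(seed = 24, positiveFraction = 0.4,
                           colorNoiseSd = 8)
  cl <- clusterPixels(tile$rgb, K = 4, seed = 24)
  mp <- matchCentroids(cl$centroids, tile$truth@classColors)
  relabel <- integer(4); relabel[mp] <- 1:4
  agree <- mean(relabel[cl$classLabels] == tile$truth@classMap)
  expect_gte(agree, 0.99)
  cls <- classifyIHC(tile$rgb, seed = 24)
  expect_lt(abs(negativeFraction(cls) -
                (1 - tile$truth@positiveFractionTruth)), 0.02)
})

test_that("pixel order does not matter and relabelling preserves the fraction", {
  tile <- simulateIHCScene(seed = 25, imageShape = c(48, 48),
                           positiveFraction = 0.35, colorNoiseSd = 0)
  cls <- classifyIHC(tile$rgb, seed = 25)
  perm <- withr::with_seed(1, sample(48 * 48))
  shuffled <- array(0L, dim(tile$rgb))
  for (ch in 1:3) {
    shuffled[, , ch] <- matrix(as.vector(tile$rgb[, , ch])[perm], 48, 48)
  }
  cls2 <- classifyIHC(shuffled, seed = 25)
  expect_equal(negativeFraction(cls2), negativeFraction(cls),
               tolerance = 1e-12)
})

test_that("negative fraction decreases as positive pixels increase", {
  base <- matrix(2L, 10, 10)          # all hematoxylin tissue
  fr <- vapply(c(5L, 20L, 60L), function(nPos) {
    lab <- base
    lab[seq_len(nPos)] <- 1L
    negativePixelFraction(lab, 1L, 3L)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("condition comparison delegates to the Mann-Whitney test", {
  a <- c(0.71, 0.64, 0.69, 0.66); b <- c(0.45, 0.52, 0.48, 0.50)
  res <- compareConditions(a, b)
  expect_s4_class(res, "TestResult")
  expect_equal(pValue(res), pValue(mannWhitneyU(a, b)))
})
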