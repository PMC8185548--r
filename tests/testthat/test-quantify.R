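twoCellSet <- function() {
  # two 20x20-px square territories sharing a 20x5 strip on a 64x64 grid
  nr <- 64
  m <- matrix(0L, nr, 64)
  aIdx <- which(row(m) %in% 21:40 & col(m) %in% 11:30)
  bIdx <- which(row(m) %in% 21:40 & col(m) %in% 26:45)
  cover <- matrix(0L, nr, 64)
  cover[aIdx] <- cover[aIdx] + 1L
  cover[bIdx] <- cover[bIdx] + 1L
  new("CellTerritorySet", territories = list(sort(aIdx), sort(bIdx)),
      coverCount = cover, cellIds = 1:2, ringRadiusPx = 1,
      nucleusArea = c(1L, 1L), centroidRow = c(30, 30),
      centroidCol = c(20, 36), touchesBorder = c(FALSE, FALSE))
}

test_that("background estimators: median of outside pixels, mode, percentile", {
  ts <- twoCellSet()
  const <- ChannelImage(matrix(7, 64, 64))
  expect_equal(estimateBackground(const, ts), 7)
  # engineer the outside multiset to start {1,2,3,4,100}
  px <- matrix(3, 64, 64)
  outside <- which(coverCount(ts) == 0L)
  px[outside] <- 3
  px[outside[1:4]] <- c(1, 2, 4, 100)
  # median of {1,2,4,100, 3,3,3,...} is 3
  expect_equal(estimateBackground(ChannelImage(px), ts), 3)
  expect_equal(estimateBackground(ChannelImage(px), ts, method = "mode"), 3)
  expect_equal(
    estimateBackground(ChannelImage(px), ts, method = "percentile",
                       percentile = 1), 100)
  # whole-image coverage is an error pointing at the explicit override
  full <- new("CellTerritorySet", territories = list(seq_len(16)),
              coverCount = matrix(1L, 4, 4), cellIds = 1L, ringRadiusPx = 1,
              nucleusArea = 16L, centroidRow = 2.5, centroidCol = 2.5,
              touchesBorder = TRUE)
  expect_error(estimateBackground(ChannelImage(matrix(1, 4, 4)), full),
               "explicit background")
})

test_that("background estimate recovers the generator's level", {
  sc <- simulatePLAScene(seed = 13, nNuclei = 4, noiseSd = 2,
                         backgroundLevel = 50)
  q <- quantifyScene(sc)
  expect_lt(abs(q$b - 50), 1)
})

test_that("uniform image equal to the background cancels exactly", {
  ts <- twoCellSet()
  rec <- quantifyCells(ChannelImage(matrix(9, 64, 64)), ts, 9)
  expect_equal(rec$corrected_intensity, c(0, 0))
})

test_that("a shared region's intensity is split evenly between the cells", {
  ts <- twoCellSet()
  px <- matrix(0, 64, 64)
  A <- 300; B <- 500; S <- 120
  shared <- which(coverCount(ts) == 2L)
  onlyA <- setdiff(territoryPixels(ts)[[1]], shared)
  onlyB <- setdiff(territoryPixels(ts)[[2]], shared)
  px[onlyA] <- A / length(onlyA)
  px[onlyB] <- B / length(onlyB)
  px[shared] <- S / length(shared)
  rec <- quantifyCells(ChannelImage(px), ts, 0)
  expect_equal(rec$corrected_intensity, c(A + S / 2, B + S / 2))
})

test_that("corrected = raw - b * weighted area, row by row", {
  sc <- simulatePLAScene(seed = 14, nNuclei = 4, nTouchingPairs = 1)
  q <- quantifyScene(sc)
  expect_equal(q$cells$corrected_intensity,
               q$cells$raw_intensity - q$b * q$cells$territory_area_px)
})

test_that("even splitting conserves total background-subtracted intensity", {
  for (s in 1:3) {
    sc <- simulatePLAScene(seed = 60 + s, nNuclei = 4, nTouchingPairs = 2)
    q <- quantifyScene(sc, ringRadiusPx = 25)   # wide rings force overlap
    I <- pixels(sc$pla)
    covered <- coveredMask(q$territories)
    expect_equal(sum(q$cells$corrected_intensity),
                 sum(I[covered] - q$b), tolerance = 1e-9)
  }
})

test_that("adding intensity to an exclusive pixel moves only that cell", {
  ts <- twoCellSet()
  px <- matrix(5, 64, 64)
  base <- quantifyCells(ChannelImage(px), ts, 2)
  excl <- setdiff(territoryPixels(ts)[[1]], which(coverCount(ts) == 2L))[1]
  px[excl] <- px[excl] + 40
  bumped <- quantifyCells(ChannelImage(px), ts, 2)
  expect_equal(bumped$corrected_intensity[1],
               base$corrected_intensity[1] + 40)
  expect_equal(bumped$corrected_intensity[2], base$corrected_intensity[2])
})

test_that("a background error shifts equal-area cells equally", {
  ts <- twoCellSet()
  set.seed(77)
  px <- matrix(rexp(64 * 64, 1 / 20), 64, 64)
  r1 <- quantifyCells(ChannelImage(px), ts, 10)
  r2 <- quantifyCells(ChannelImage(px), ts, 14)
  expect_equal(diff(r1$corrected_intensity), diff(r2$corrected_intensity))
})

test_that("shape mismatch between image and territories is an error", {
  ts <- twoCellSet()
  expect_error(quantifyCells(ChannelImage(matrix(1, 32, 32)), ts, 0),
               "shape")
})

test_that("condition distributions report mean and population SD", {
  d <- perCellDistribution(c(1, 2, 3), "ctrl")
  expect_equal(d$mean, 2)
  expect_equal(d$sd, sqrt(2 / 3))          # population SD ~ 0.8165
  expect_equal(perCellDistribution(5)$sd, 0)
  expect_error(perCellDistribution(numeric(0)), "no per-cell records")
})

test_that("per-cell means concentrate on the generated truth", {
  vals <- numeric(0)
  for (s in 1:6) {
    sc <- simulatePLAScene(seed = 500 + s, nNuclei = 6)
    q <- quantifyScene(sc, background = 200)
    vals <- c(vals, q$cells$corrected_intensity)
  }
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 50000), 3 * se + 0.01 * 50000)
})
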