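test_that("a zero-signal scene renders an identically zero PLA channel", {
  sc <- simulatePLAScene(seed = 1, imageShape = c(64, 64),
                         nuclei = cbind(32, 32, 8), perCellTotal = 0,
                         backgroundLevel = 0, noiseSd = 0,
                         territoryRingPx = 10)
  expect_true(all(pixels(sc$pla) == 0))
})

test_that("rendered PLA intensity integrates to the requested per-cell total", {
  sc <- simulatePLAScene(seed = 2, imageShape = c(64, 64),
                         nuclei = cbind(32, 32, 8), perCellTotal = 1000,
                         backgroundLevel = 0, noiseSd = 0,
                         territoryRingPx = 10)
  expect_equal(sum(pixels(sc$pla)), 1000, tolerance = 1e-9)
  # multi-cell scene: per-cell integral inside nucleus + ring within 1%
  # (Gaussian-tail truncation only)
  sc2 <- simulatePLAScene(seed = 5, nNuclei = 3, noiseSd = 0,
                          backgroundLevel = 0)
  I <- pixels(sc2$pla)
  tr <- sc2$truth
  for (i in seq_len(nrow(tr@nuclei))) {
    d <- sqrt((row(I) - tr@nuclei[i, 1])^2 + (col(I) - tr@nuclei[i, 2])^2)
    inside <- sum(I[d <= tr@territoryRadiusPx[i]])
    expect_gt(inside, 0.99 * tr@perCellTotal[i])
    expect_lte(inside, tr@perCellTotal[i] + 1e-6)
  }
})

test_that("identical seed and parameters give bit-identical scenes", {
  a <- simulatePLAScene(seed = 11, nNuclei = 4, nTouchingPairs = 1)
  b <- simulatePLAScene(seed = 11, nNuclei = 4, nTouchingPairs = 1)
  expect_identical(pixels(a$hoechst), pixels(b$hoechst))
  expect_identical(pixels(a$pla), pixels(b$pla))
  expect_identical(a$truth@nuclei, b$truth@nuclei)
  c <- simulatePLAScene(seed = 12, nNuclei = 4, nTouchingPairs = 1)
  expect_false(identical(pixels(a$pla), pixels(c$pla)))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulatePLAScene(seed = 3, nNuclei = 2))
  expect_identical(.Random.seed, before)
})

test_that("undeclared overlapping nuclei are rejected", {
  nuc <- rbind(c(40, 40, 10), c(40, 52, 10))   # 12 px apart, radii sum 20
  expect_error(
    simulatePLAScene(seed = 1, imageShape = c(96, 96), nuclei = nuc),
    "not declared")
  # declaring the pair legitimises it
  sc <- simulatePLAScene(seed = 1, imageShape = c(96, 96), nuclei = nuc,
                         touchingPairs = rbind(c(1L, 2L)))
  expect_identical(nrow(sc$truth@nuclei), 2L)
})

test_that("noiseless IHC tiles realise the positive fraction exactly", {
  tile <- simulateIHCScene(seed = 4, imageShape = c(64, 64),
                           positiveFraction = 0.5, colorNoiseSd = 0)
  tr <- tile$truth
  tissue <- tr@classMap != 3L
  expect_identical(sum(tr@classMap == 1L) / sum(tissue),
                   tr@positiveFractionTruth)
  expect_equal(tr@positiveFractionTruth, 0.5, tolerance = 1e-3)
  # exact colour matching on the emitted image reproduces the truth
  cols <- tr@classColors
  isDab <- tile$rgb[, , 1] == cols[1, 1] & tile$rgb[, , 2] == cols[1, 2] &
           tile$rgb[, , 3] == cols[1, 3]
  isWhite <- tile$rgb[, , 1] == cols[3, 1] & tile$rgb[, , 2] == cols[3, 2] &
             tile$rgb[, , 3] == cols[3, 3]
  expect_identical(sum(isDab) / sum(!isWhite), tr@positiveFractionTruth)
  # zero-DAB all-tissue tile
  t0 <- simulateIHCScene(seed = 5, imageShape = c(64, 64),
                         backgroundFraction = 0, positiveFraction = 0,
                         colorNoiseSd = 0)
  expect_identical(t0$truth@positiveFractionTruth, 0)
})

test_that("sub-separable colour spacing is flagged and warned about", {
  expect_warning(
    tile <- simulateIHCScene(seed = 6, imageShape = c(64, 64),
                             colorNoiseSd = 40),
    "not guaranteed")
  expect_false(tile$truth@separable)
  expect_true(simulateIHCScene(seed = 6, imageShape = c(64, 64),
                               colorNoiseSd = 8)$truth@separable)
})

test_that("rejection cohorts: degenerate probabilities, determinism, moments", {
  t01 <- simulateRejectionCohort(seed = 1, nPerGroup = 5, pReject = c(0, 1))
  expect_identical(unname(t01), rbind(c(0L, 5L), c(5L, 0L)))
  expect_identical(simulateRejectionCohort(seed = 9),
                   simulateRejectionCohort(seed = 9))
  # binomial moments at the tumour-rejection rates: mean rejected counts
  # approach (4, 15) per 20 animals
  reps <- 2000L
  rej <- vapply(seq_len(reps), function(i) {
    simulateRejectionCohort(seed = 10000 + i)[, 1]
  }, numeric(2))
  se1 <- sqrt(0.2 * 0.8 * 20 / reps)
  se2 <- sqrt(0.75 * 0.25 * 20 / reps)
  expect_lt(abs(mean(rej[1, ]) - 4), 3 * se1)
  expect_lt(abs(mean(rej[2, ]) - 15), 3 * se2)
})
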