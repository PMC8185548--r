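#' Simulate a two-channel PLA scene with exhaustive ground truth
#'
#' Renders a field of round, partially touching nuclei (Hoechst channel) and
#' punctate PLA signal (PLA channel) with a known integrated intensity per
#' cell, so that segmentation, territory construction and per-cell
#' quantification can all be validated against truth.
#'
#' Nuclei are hard disks of plateau intensity \code{nucleusLevel} smoothed by
#' a small Gaussian (sigma = 1 px), giving the mean + k SD threshold a sharp
#' recovery target. Each cell's PLA signal is a set of Gaussian puncta whose
#' centres are drawn uniformly inside the cell's prospective territory (a
#' disk of radius nucleus radius + \code{territoryRingPx}, shrunk by 3 spot
#' sigmas so the tails stay inside); punctum amplitudes are normalised so
#' the rendered per-cell sum equals \code{perCellTotal} exactly before
#' background and noise. Noise is additive Gaussian, clipped at zero;
#' intensities live on a 16-bit-style count scale.
#'
#' Geometry defaults describe a desk-scale field: 256 x 256 px at
#' 0.5 um/px with 10 px (5 um) nucleus radii and a 17 px (8.5 um) ring.
#'
#' @param seed integer; the only source of randomness (global RNG state is
#'   untouched).
#' @param imageShape integer (rows, cols), at least 64 x 64.
#' @param pixelSizeUm physical pixel size.
#' @param nuclei optional n x 3 matrix (centerRow, centerCol, radiusPx). When
#'   supplied, \code{touchingPairs} must declare every pair of nuclei closer
#'   than the sum of their radii; an undeclared overlap is an error because
#'   its ground truth would be ambiguous.
#' @param nNuclei,nucleusRadiusPx number and radius of auto-placed isolated
#'   nuclei (ignored when \code{nuclei} is given).
#' @param nTouchingPairs number of auto-placed touching pairs, centres
#'   \code{touchingSepFactor} radii apart.
#' @param touchingPairs 2-column matrix of declared touching index pairs
#'   (for user-supplied \code{nuclei}).
#' @param touchingSepFactor centre separation of auto-placed pairs in units
#'   of the nucleus radius (default 1.5: one merged blob before watershed).
#' @param perCellTotal integrated PLA intensity per cell (counts); scalar or
#'   one value per cell; must be >= 0.
#' @param punctaPerCell,punctumSigmaPx puncta per cell and Gaussian spot SD.
#' @param territoryRingPx ring width used for punctum placement.
#' @param nucleusLevel Hoechst plateau intensity of a nucleus.
#' @param backgroundLevel uniform background added to both channels.
#' @param noiseSd additive Gaussian noise SD (both channels).
#' @return list with elements \code{hoechst} and \code{pla} (both
#'   \linkS4class{ChannelImage}) and \code{truth}
#'   (\linkS4class{PLASceneTruth}).
#' @examples
#' sc <- simulatePLAScene(seed = 1, nNuclei = 3)
#' sc$truth
#' @export
simulatePLAScene <- function(seed,
                             imageShape = c(256L, 256L),
                             pixelSizeUm = 0.5,
                             nuclei = NULL,
                             nNuclei = 6L,
                             nucleusRadiusPx = 10,
                             nTouchingPairs = 0L,
                             touchingPairs = NULL,
                             touchingSepFactor = 1.5,
                             perCellTotal = 50000,
                             punctaPerCell = 20L,
                             punctumSigmaPx = 1.2,
                             territoryRingPx = 17,
                             nucleusLevel = 3000,
                             backgroundLevel = 200,
                             noiseSd = 60) {
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2L || any(imageShape < 64L)) {
    stop("'imageShape' must be (rows, cols) with both >= 64")
  }
  withSeed(seed, {
    if (is.null(nuclei)) {
      placed <- placeNuclei(imageShape, nNuclei, nucleusRadiusPx,
                            nTouchingPairs, touchingSepFactor,
                            territoryRingPx)
      nuclei <- placed$nuclei
      touchingPairs <- placed$pairs
    } else {
      nuclei <- as.matrix(nuclei)
      if (ncol(nuclei) != 3L || nrow(nuclei) < 1L) {
        stop("'nuclei' must be an n x 3 matrix (row, col, radius)")
      }
      if (is.null(touchingPairs)) {
        touchingPairs <- matrix(integer(0), ncol = 2L)
      }
      checkUndeclaredOverlap(nuclei, touchingPairs)
    }
    n <- nrow(nuclei)
    if (any(nuclei[, 3] <= 0)) stop("nucleus radii must be > 0")
    if (any(nuclei[, 1] < 1 | nuclei[, 1] > imageShape[1] |
            nuclei[, 2] < 1 | nuclei[, 2] > imageShape[2])) {
      stop("all nucleus centres must lie inside the image")
    }
    perCellTotal <- rep_len(perCellTotal, n)
    if (any(perCellTotal < 0)) stop("'perCellTotal' must be >= 0")

    hoechst <- renderNuclei(imageShape, nuclei, nucleusLevel)
    pla <- matrix(0, imageShape[1], imageShape[2])
    for (i in seq_len(n)) {
      pla <- pla + renderPuncta(imageShape, nuclei[i, ], perCellTotal[i],
                                punctaPerCell, punctumSigmaPx,
                                territoryRingPx)
    }
    npix <- prod(imageShape)
    hoechst <- hoechst + backgroundLevel
    pla <- pla + backgroundLevel
    if (noiseSd > 0) {
      hoechst <- hoechst + rnorm(npix, 0, noiseSd)
      pla <- pla + rnorm(npix, 0, noiseSd)
    }
    hoechst[hoechst < 0] <- 0
    pla[pla < 0] <- 0

    truth <- new("PLASceneTruth",
      imageShape = imageShape, pixelSizeUm = pixelSizeUm,
      nuclei = nuclei,
      touchingPairs = matrix(as.integer(touchingPairs), ncol = 2L),
      perCellTotal = perCellTotal,
      punctaPerCell = as.integer(punctaPerCell),
      punctumSigmaPx = punctumSigmaPx,
      territoryRadiusPx = nuclei[, 3] + territoryRingPx,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      seed = as.integer(seed))
    list(
      hoechst = ChannelImage(hoechst, pixelSizeUm, "hoechst"),
      pla     = ChannelImage(pla, pixelSizeUm, "pla"),
      truth   = truth
    )
  })
}

setMethod("show", "PLASceneTruth", function(object) {
  cat(sprintf(
    "PLASceneTruth: %d x %d px, %d nucle%s (%d touching pair%s), seed %d\n",
    object@imageShape[1], object@imageShape[2], nrow(object@nuclei),
    if (nrow(object@nuclei) == 1L) "us" else "i",
    nrow(object@touchingPairs),
    if (nrow(object@touchingPairs) == 1L) "" else "s", object@seed))
})

# rejection-sample nucleus centres: isolated nuclei pairwise separated by
# at least 2r + 8 px (so thresholded blobs stay disjoint), touching pairs
# at sepFactor * r; everything at least radius + ring from the border so
# puncta and the smoothed rim stay in-frame
placeNuclei <- function(shape, nSingle, r, nPairs, sepFactor, ringPx) {
  margin <- ceiling(r + ringPx + 2)
  lo <- c(margin, margin); hi <- shape - margin
  if (any(hi <= lo)) stop("image too small for the requested geometry")
  minSep <- 2 * r + 8
  centres <- matrix(numeric(0), ncol = 2L)
  pairs <- matrix(integer(0), ncol = 2L)
  groups <- list()
  for (g in seq_len(nSingle)) groups[[length(groups) + 1L]] <- "single"
  for (g in seq_len(nPairs))  groups[[length(groups) + 1L]] <- "pair"
  for (g in groups) {
    ok <- FALSE
    for (try in 1:2000) {
      c0 <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      cand <- if (g == "single") rbind(c0) else {
        ang <- runif(1, 0, 2 * pi)
        rbind(c0, c0 + sepFactor * r * c(cos(ang), sin(ang)))
      }
      if (any(cand[, 1] < lo[1] | cand[, 1] > hi[1] |
              cand[, 2] < lo[2] | cand[, 2] > hi[2])) next
      if (nrow(centres) > 0L) {
        d <- sqrt(outer(cand[, 1], centres[, 1], "-")^2 +
                  outer(cand[, 2], centres[, 2], "-")^2)
        if (min(d) < minSep) next
      }
      if (g == "pair") {
        pairs <- rbind(pairs, nrow(centres) + c(1L, 2L))
      }
      centres <- rbind(centres, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place nuclei without undeclared overlap; ",
                  "reduce counts or enlarge the image")
  }
  list(nuclei = cbind(centres, r), pairs = pairs)
}

checkUndeclaredOverlap <- function(nuclei, pairs) {
  n <- nrow(nuclei)
  if (n < 2L) return(invisible(NULL))
  declared <- apply(matrix(as.integer(pairs), ncol = 2L), 1L,
                    function(p) paste(sort(p), collapse = "-"))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((nuclei[i, 1:2] - nuclei[j, 1:2])^2))
    if (d < nuclei[i, 3] + nuclei[j, 3] &&
        !(paste(i, j, sep = "-") %in% declared)) {
      stop(sprintf(
        "nuclei %d and %d overlap but are not declared in 'touchingPairs'",
        i, j))
    }
  }
  invisible(NULL)
}

# hard disks at `level`, smoothed by a sigma = 1 px Gaussian
renderNuclei <- function(shape, nuclei, level) {
  img <- matrix(0, shape[1], shape[2])
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(nuclei))) {
    img[(rr - nuclei[i, 1])^2 + (cc - nuclei[i, 2])^2 <= nuclei[i, 3]^2] <- 1
  }
  as.matrix(EBImage::gblur(img, sigma = 1)) * level
}

# Gaussian puncta for one cell, total integrated intensity scaled to
# exactly `total`
renderPuncta <- function(shape, nucleus, total, k, sigma, ringPx) {
  img <- matrix(0, shape[1], shape[2])
  if (total <= 0 || k < 1L) return(img)
  rPlace <- max(nucleus[3] + ringPx - 3 * sigma, 1)
  rad <- rPlace * sqrt(runif(k))
  ang <- runif(k, 0, 2 * pi)
  pr <- nucleus[1] + rad * cos(ang)
  pc <- nucleus[2] + rad * sin(ang)
  w <- ceiling(4 * sigma)
  for (p in seq_len(k)) {
    r0 <- max(1, floor(pr[p] - w)); r1 <- min(shape[1], ceiling(pr[p] + w))
    c0 <- max(1, floor(pc[p] - w)); c1 <- min(shape[2], ceiling(pc[p] + w))
    gr <- exp(-((r0:r1) - pr[p])^2 / (2 * sigma^2))
    gc <- exp(-((c0:c1) - pc[p])^2 / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + outer(gr, gc)
  }
  img * (total / sum(img))
}
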