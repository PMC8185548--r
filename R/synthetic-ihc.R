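#' Simulate a brightfield IHC tile with known class composition
#'
#' Builds an RGB tile from four colour populations — DAB brown
#' (calreticulin-positive), hematoxylin blue (negative tissue), white slide
#' background, and one intermediate mixed class — with exact pixel counts per
#' class, then adds per-channel Gaussian noise and clamps to [0, 255]. The
#' ground-truth positive fraction is the DAB share of the tissue (non-white)
#' pixels, computed from the emitted class map, so it is exact by
#' construction.
#'
#' Class positions are a random permutation of the pixel grid: K-means colour
#' clustering is blind to spatial arrangement, so spatial texture is not
#' modelled.
#'
#' @param seed integer seed (sole source of randomness).
#' @param imageShape integer (rows, cols).
#' @param classColors 4 x 3 RGB matrix in the fixed order DAB, hematoxylin,
#'   white, intermediate.
#' @param backgroundFraction white (non-tissue) share of all pixels.
#' @param positiveFraction target DAB share of tissue pixels; realised
#'   exactly up to one pixel of rounding and reported exactly in the truth.
#' @param intermediateFraction intermediate-class share of the non-DAB
#'   tissue pixels (so any \code{positiveFraction} in [0, 1] is valid).
#' @param colorNoiseSd per-channel Gaussian noise SD. When the minimum
#'   pairwise distance between class colours is not larger than
#'   6 * colorNoiseSd the tile is outside the separable regime: the truth is
#'   flagged (\code{separable = FALSE}) and a warning is raised, since
#'   clustering recovery is then not guaranteed.
#' @return list with \code{rgb} (rows x cols x 3 integer array, 0..255) and
#'   \code{truth} (\linkS4class{IHCSceneTruth}).
#' @examples
#' tile <- simulateIHCScene(seed = 3, positiveFraction = 0.3)
#' tile$truth
#' @export
simulateIHCScene <- function(seed,
                             imageShape = c(256L, 256L),
                             classColors = ihcReferenceColors(),
                             backgroundFraction = 0.25,
                             positiveFraction = 0.4,
                             intermediateFraction = 0.2,
                             colorNoiseSd = 8) {
  imageShape <- as.integer(imageShape)
  classColors <- as.matrix(classColors)
  if (nrow(classColors) != 4L || ncol(classColors) != 3L) {
    stop("'classColors' must be a 4 x 3 RGB matrix")
  }
  if (anyDuplicated(classColors)) stop("the 4 class colours must be distinct")
  if (positiveFraction < 0 || positiveFraction > 1 ||
      backgroundFraction < 0 || backgroundFraction >= 1) {
    stop("fractions must lie in [0, 1] (background < 1)")
  }
  dmin <- min(stats::dist(classColors))
  separable <- dmin > 6 * colorNoiseSd
  if (!separable) {
    warning("class colours are closer than 6 x colorNoiseSd; ",
            "clustering recovery is not guaranteed")
  }
  withSeed(seed, {
    npix <- prod(imageShape)
    nWhite <- round(backgroundFraction * npix)
    nTissue <- npix - nWhite
    if (nTissue < 1L) stop("tile must contain at least one tissue pixel")
    nDab <- round(positiveFraction * nTissue)
    nInt <- round(intermediateFraction * (nTissue - nDab))
    nHem <- nTissue - nDab - nInt
    cls <- sample(rep.int(1:4, c(nDab, nHem, nWhite, nInt)))
    classMap <- matrix(as.integer(cls), imageShape[1], imageShape[2])
    rgb <- array(0, c(imageShape, 3L))
    for (ch in 1:3) {
      plane <- classColors[cls, ch]
      if (colorNoiseSd > 0) plane <- plane + rnorm(npix, 0, colorNoiseSd)
      rgb[, , ch] <- matrix(plane, imageShape[1], imageShape[2])
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))
    storage.mode(rgb) <- "integer"
    truth <- new("IHCSceneTruth",
      imageShape = imageShape, classColors = classColors,
      classMap = classMap,
      positiveFractionTruth = nDab / nTissue,
      colorNoiseSd = colorNoiseSd, separable = separable,
      seed = as.integer(seed))
    list(rgb = rgb, truth = truth)
  })
}

#' Default IHC class colours
#'
#' DAB brown, hematoxylin blue, white slide background and a pink-ish
#' intermediate class, on the 0..255 RGB scale.
#' @return a named 4 x 3 matrix.
#' @export
ihcReferenceColors <- function() {
  rbind(dab          = c(120,  80,  45),
        hematoxylin  = c( 60,  60, 150),
        white        = c(255, 255, 255),
        intermediate = c(220, 180, 190))
}

setMethod("show", "IHCSceneTruth", function(object) {
  cat(sprintf(
    "IHCSceneTruth: %d x %d px, positive fraction %.4f, noise SD %g%s, seed %d\n",
    object@imageShape[1], object@imageShape[2],
    object@positiveFractionTruth, object@colorNoiseSd,
    if (object@separable) "" else " (NOT separable)", object@seed))
})

#' Simulate a tumour-rejection cohort as a 2 x 2 contingency table
#'
#' Draws the number of rejecting animals in each of two groups from
#' independent binomials and returns the 2 x 2 table (rows = groups,
#' columns = rejected / not rejected) that a Fisher exact test consumes.
#'
#' @param seed integer seed.
#' @param nPerGroup animals per group (single integer or length 2).
#' @param pReject length-2 vector of per-group rejection probabilities.
#' @return 2 x 2 integer matrix with dimnames.
#' @examples
#' simulateRejectionCohort(seed = 1, nPerGroup = 20, pReject = c(0.2, 0.75))
#' @export
simulateRejectionCohort <- function(seed, nPerGroup = 20L,
                                    pReject = c(0.2, 0.75)) {
  nPerGroup <- rep_len(as.integer(nPerGroup), 2L)
  if (any(nPerGroup < 1L)) stop("'nPerGroup' must be >= 1")
  if (length(pReject) != 2L || any(pReject < 0 | pReject > 1)) {
    stop("'pReject' must be two probabilities in [0, 1]")
  }
  withSeed(seed, {
    rej <- rbinom(2L, nPerGroup, pReject)
    matrix(as.integer(c(rej[1], nPerGroup[1] - rej[1],
                        rej[2], nPerGroup[2] - rej[2])),
           nrow = 2L, byrow = TRUE,
           dimnames = list(group = c("group1", "group2"),
                           outcome = c("rejected", "not_rejected")))
  })
}
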