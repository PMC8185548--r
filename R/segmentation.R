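#' Global intensity threshold: mean + k standard deviations
#'
#' The nuclear mask threshold is the mean image intensity plus
#' \code{thresholdK} times the population standard deviation (divisor n) of
#' all pixels of that image. Statistics are per image, not per experiment.
#'
#' @param img a \linkS4class{ChannelImage}.
#' @param thresholdK SD multiplier (default 2).
#' @return the scalar threshold. The mask convention everywhere in the
#'   package is strictly greater than the threshold, so a constant image
#'   yields an empty mask.
#' @examples
#' img <- ChannelImage(matrix(c(rep(0, 8), 10), 3, 3))
#' globalThreshold(img)   # 10/9 + 2 * population SD
#' @export
globalThreshold <- function(img, thresholdK = 2) {
  stopifnot(is(img, "ChannelImage"))
  if (thresholdK < 0) stop("'thresholdK' must be >= 0")
  p <- img@pixels
  mean(p) + thresholdK * popSd(p)
}

#' Segmentation parameter bundle
#'
#' Collects the tunables of [segmentNuclei()] with the defaults used
#' throughout: threshold multiplier 2; size bounds and seed separation
#' derived from the data when \code{NULL} (see the parameter notes);
#' hole-filling on, so dim chromocenters do not punch holes into nucleus
#' intensity sums.
#'
#' @param thresholdK SD multiplier for the global threshold.
#' @param minAreaPx,maxAreaPx accepted component area bounds in pixels.
#'   When \code{NULL}, bounds default to 25\% and 400\% of the median
#'   component area measured on the pre-filter (post-watershed) components.
#' @param minSeedDistPx minimum Euclidean separation between watershed
#'   seeds. When \code{NULL}, defaults to 0.7 x the median component
#'   equivalent radius \eqn{\sqrt{A/\pi}} of the pre-watershed components.
#' @param fillHoles fill holes in the binary mask before watershed.
#' @return a named list of class \code{"SegmentationParams"}.
#' @export
segmentationParams <- function(thresholdK = 2, minAreaPx = NULL,
                               maxAreaPx = NULL, minSeedDistPx = NULL,
                               fillHoles = TRUE) {
  if (!is.null(minAreaPx) && !is.null(maxAreaPx) &&
      !(minAreaPx > 0 && minAreaPx < maxAreaPx)) {
    stop("need 0 < minAreaPx < maxAreaPx")
  }
  structure(list(thresholdK = thresholdK, minAreaPx = minAreaPx,
                 maxAreaPx = maxAreaPx, minSeedDistPx = minSeedDistPx,
                 fillHoles = fillHoles),
            class = "SegmentationParams")
}

#' Segment nuclei from the Hoechst channel
#'
#' The pipeline is: binary mask at the global mean + k SD threshold
#' (strictly greater); optional hole filling; Euclidean distance transform;
#' seeds at distance-transform local maxima thinned to a minimum pairwise
#' separation (strongest first, ties by raster position); seeded watershed
#' (region growing from the seeds restricted to the mask), which splits most
#' touching nuclei; size filtering; deterministic renumbering 1..n in
#' raster-scan order of each region's top-left pixel.
#'
#' Components are 8-connected. An image with no pixel above threshold yields
#' a valid empty \linkS4class{LabelMap} (\code{nCells = 0}), not an error.
#'
#' @param img Hoechst \linkS4class{ChannelImage}.
#' @param params a [segmentationParams()] bundle.
#' @return a \linkS4class{LabelMap}; the threshold used is attached as
#'   attribute \code{"threshold"}.
#' @examples
#' sc <- simulatePLAScene(seed = 7, nNuclei = 4)
#' lm <- segmentNuclei(sc$hoechst)
#' nCells(lm)
#' @export
segmentNuclei <- function(img, params = segmentationParams()) {
  stopifnot(is(img, "ChannelImage"))
  thr <- globalThreshold(img, params$thresholdK)
  mask <- img@pixels > thr
  empty <- function() {
    out <- new("LabelMap", labels = matrix(0L, nrow(mask), ncol(mask)),
               nCells = 0L)
    attr(out, "threshold") <- thr
    out
  }
  if (!any(mask)) return(empty())
  if (isTRUE(params$fillHoles)) {
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  comps <- label8(mask)
  nComp <- max(comps)
  compArea <- tabulate(comps[comps > 0L], nbins = nComp)

  minSeed <- params$minSeedDistPx
  if (is.null(minSeed)) {
    minSeed <- 0.7 * sqrt(stats::median(compArea) / pi)
  }
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  # local maxima of the distance transform (3 x 3 max filter)
  dtmax <- as.matrix(EBImage::dilate(EBImage::Image(dt),
                                     EBImage::makeBrush(3, "box")))
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  nextLab <- 0L
  for (k in seq_len(nComp)) {
    inComp <- comps == k
    cand <- which(inComp & dt >= dtmax - 1e-9)
    kept <- suppressMaxima(cand, dt[cand], nrow(mask), minSeed)
    seeds[kept] <- nextLab + seq_along(kept)
    nextLab <- nextLab + length(kept)
  }
  ws <- as.matrix(EBImage::propagate(EBImage::Image(dt),
                                     EBImage::Image(seeds), mask = mask))
  ws <- matrix(as.integer(round(ws)), nrow(mask), ncol(mask))

  regArea <- tabulate(ws[ws > 0L], nbins = max(ws))
  minA <- params$minAreaPx
  maxA <- params$maxAreaPx
  medA <- stats::median(regArea[regArea > 0])
  if (is.null(minA)) minA <- 0.25 * medA
  if (is.null(maxA)) maxA <- 4 * medA
  drop <- which(regArea < minA | regArea > maxA)
  ws[ws %in% drop] <- 0L
  out <- LabelMap(ws)
  attr(out, "threshold") <- thr
  out
}

#' Per-nucleus geometry table
#'
#' @param labels a \linkS4class{LabelMap}.
#' @return data.frame with one row per cell: \code{label},
#'   \code{centroid_row}, \code{centroid_col}, \code{area_px}.
#' @export
nucleiTable <- function(labels) {
  stopifnot(is(labels, "LabelMap"))
  l <- labels@labels
  n <- labels@nCells
  if (n == 0L) {
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0)))
  }
  idx <- which(l > 0L)
  lab <- l[idx]
  r <- (idx - 1L) %% nrow(l) + 1L
  c <- (idx - 1L) %/% nrow(l) + 1L
  data.frame(
    label = seq_len(n),
    centroid_row = as.numeric(tapply(r, lab, mean)),
    centroid_col = as.numeric(tapply(c, lab, mean)),
    area_px = as.integer(tabulate(lab, nbins = n))
  )
}
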