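#' Construct a ChannelImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSizeUm physical pixel size in micrometres.
#' @param channelName channel tag.
#' @return a \linkS4class{ChannelImage}.
#' @examples
#' img <- ChannelImage(matrix(runif(64), 8, 8), pixelSizeUm = 0.5)
#' pixelSizeUm(img)
#' @export
ChannelImage <- function(pixels, pixelSizeUm = 1, channelName = "unnamed") {
  new("ChannelImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm),
      channelName = as.character(channelName))
}

#' @rdname ChannelImage
#' @export
setMethod("pixels", "ChannelImage", function(x) x@pixels)

#' @rdname ChannelImage
#' @export
setMethod("pixelSizeUm", "ChannelImage", function(x) x@pixelSizeUm)

#' @rdname ChannelImage
#' @export
setMethod("channelName", "ChannelImage", function(x) x@channelName)

#' @rdname ChannelImage
#' @export
setMethod("dim", "ChannelImage", function(x) dim(x@pixels))

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ChannelImage '%s': %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              object@channelName, d[1], d[2], object@pixelSizeUm,
              min(object@pixels), max(object@pixels)))
})

#' Construct a LabelMap from an integer label matrix
#'
#' Renumbers the positive labels to 1..n in raster-scan order of each
#' region's top-left pixel (topmost, then leftmost), so the numbering is a
#' deterministic function of the region geometry alone.
#'
#' @param labels matrix of non-negative integer labels (0 = background).
#' @return a \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  new("LabelMap", labels = renumberRaster(labels),
      nCells = length(unique(labels[labels > 0L])))
}

# relabel positive regions 1..n by raster order (row-major) of the
# topmost-then-leftmost pixel of each region
renumberRaster <- function(labels) {
  old <- sort(unique(labels[labels > 0L]))
  if (length(old) == 0L) return(labels)
  nc <- ncol(labels)
  key <- vapply(old, function(l) {
    idx <- which(labels == l)              # column-major linear indices
    r <- (idx - 1L) %% nrow(labels) + 1L
    c <- (idx - 1L) %/% nrow(labels) + 1L
    min((r - 1) * nc + (c - 1))            # row-major rank of top-left pixel
  }, numeric(1))
  lut <- integer(max(old))
  lut[old[order(key)]] <- seq_along(old)
  out <- labels
  out[out > 0L] <- lut[out[out > 0L]]
  out
}

#' @rdname LabelMap-class
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' @rdname LabelMap-class
#' @export
setMethod("nCells", "LabelMap", function(x) x@nCells)

#' @rdname LabelMap-class
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap: %d x %d px, %d cell(s)\n", d[1], d[2], object@nCells))
})

#' @rdname CellTerritorySet-class
#' @export
setMethod("territoryPixels", "CellTerritorySet", function(x) x@territories)

#' @rdname CellTerritorySet-class
#' @export
setMethod("coverCount", "CellTerritorySet", function(x) x@coverCount)

#' @rdname CellTerritorySet-class
#' @export
setMethod("cellIds", "CellTerritorySet", function(x) x@cellIds)

#' @rdname CellTerritorySet-class
#' @export
setMethod("ringRadiusPx", "CellTerritorySet", function(x) x@ringRadiusPx)

#' @rdname CellTerritorySet-class
#' @export
setMethod("coveredMask", "CellTerritorySet", function(x) x@coverCount > 0L)

setMethod("show", "CellTerritorySet", function(object) {
  cat(sprintf(
    "CellTerritorySet: %d territorie(s), ring radius %g px, %d covered px (%d shared)\n",
    length(object@cellIds), object@ringRadiusPx,
    sum(object@coverCount > 0L), sum(object@coverCount > 1L)))
})

#' @rdname IHCClassification-class
#' @export
setMethod("classLabels", "IHCClassification", function(x) x@classLabels)

#' @rdname IHCClassification-class
#' @export
setMethod("centroids", "IHCClassification", function(x) x@centroids)

#' @rdname IHCClassification-class
#' @export
setMethod("positiveClass", "IHCClassification", function(x) x@positiveClass)

#' @rdname IHCClassification-class
#' @export
setMethod("backgroundClass", "IHCClassification", function(x) x@backgroundClass)

#' @rdname IHCClassification-class
#' @export
setMethod("negativeFraction", "IHCClassification", function(x) x@negativeFraction)

setMethod("show", "IHCClassification", function(object) {
  cat(sprintf(
    "IHCClassification: K = %d, positive class %d, background class %d\n",
    object@K, object@positiveClass, object@backgroundClass))
  cat(sprintf("  tissue px: %d, positive px: %d, negative fraction: %.4f\n",
              object@tissuePixels, object@positivePixels,
              object@negativeFraction))
})

#' @rdname TestResult-class
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname TestResult-class
#' @export
setMethod("statistic", "TestResult", function(x) x@statistic)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n  statistic = %.6g, two-sided p = %.6g (n = %s)\n",
              object@method, object@statistic, object@pValue,
              paste(object@nPerGroup, collapse = ", ")))
})
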