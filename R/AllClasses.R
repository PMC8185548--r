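#' @import methods
NULL

#' Single-channel intensity image
#'
#' A 2D grid of non-negative fluorescence intensities together with the
#' physical pixel size. This is the common currency of the segmentation and
#' quantification stages: the Hoechst (nuclear) channel drives segmentation,
#' the PLA channel is what gets quantified per cell.
#'
#' @slot pixels numeric matrix of intensities (rows x cols), all finite and
#'   non-negative. Row/column indices are image row/column; coordinates are
#'   row-major and pixel-centered.
#' @slot pixelSizeUm physical size of one pixel in micrometres (> 0).
#' @slot channelName free-text channel tag (e.g. \code{"hoechst"},
#'   \code{"pla"}).
#'
#' @seealso [ChannelImage()] for the user-facing constructor.
#' @export
setClass("ChannelImage",
  representation(
    pixels      = "matrix",
    pixelSizeUm = "numeric",
    channelName = "character"
  ),
  prototype(pixelSizeUm = 1, channelName = "unnamed")
)

setValidity("ChannelImage", function(object) {
  p <- object@pixels
  if (length(p) == 0L) return("'pixels' must be a non-empty matrix")
  if (!is.numeric(p)) return("'pixels' must be numeric")
  if (any(!is.finite(p))) return("all intensities must be finite")
  if (any(p < 0)) return("all intensities must be >= 0")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) {
    return("'pixelSizeUm' must be a single positive number")
  }
  if (length(object@channelName) != 1L) return("'channelName' must be length 1")
  TRUE
})

#' Integer-labelled nucleus segmentation
#'
#' Labels are \code{0} for background and \code{1..nCells} for accepted
#' nuclei, with no gaps; labels are assigned in raster-scan order of each
#' region's top-left pixel so that two runs on the same input are identical.
#'
#' @slot labels integer matrix, same shape as the source image.
#' @slot nCells number of distinct positive labels.
#' @export
setClass("LabelMap",
  representation(labels = "matrix", nCells = "integer")
)

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("'labels' must be an integer matrix")
  if (any(l < 0) || any(l != round(l))) {
    return("labels must be non-negative integers")
  }
  present <- sort(unique(as.integer(l[l > 0])))
  n <- object@nCells
  if (length(n) != 1L || is.na(n)) return("'nCells' must be a single integer")
  if (length(present) != n || (n > 0L && !identical(present, seq_len(n)))) {
    return("positive labels must be exactly 1..nCells with no gaps")
  }
  TRUE
})

#' Per-cell territories with even splitting of shared pixels
#'
#' Each cell's territory is its nucleus plus the perinuclear ring obtained by
#' dilating the nucleus with a disk structuring element, clipped at the image
#' border. Where several territories cover the same pixel, that pixel's
#' intensity is split evenly: the ownership weight of pixel \eqn{p} for cell
#' \eqn{c} is \eqn{w(p,c) = 1/m(p)} with \eqn{m(p)} the number of territories
#' covering \eqn{p}, so the weights over any covered pixel sum to 1.
#'
#' Rather than storing a dense weight array per cell, the set stores each
#' territory as a vector of linear pixel indices plus one shared integer
#' cover-count matrix; weights are recovered as \code{1/coverCount}.
#'
#' @slot territories list (one element per cell, in cell-id order) of sorted
#'   integer vectors of linear pixel indices (column-major, as produced by
#'   \code{which} on a matrix).
#' @slot coverCount integer matrix, same shape as the label map; number of
#'   territories covering each pixel (0 = uncovered).
#' @slot cellIds integer vector of the cell labels, parallel to
#'   \code{territories}.
#' @slot ringRadiusPx dilation radius used, in pixels.
#' @slot nucleusArea nucleus pixel counts, parallel to \code{cellIds}.
#' @slot centroidRow,centroidCol nucleus centroids (pixel coordinates).
#' @slot touchesBorder \code{TRUE} for cells whose territory was clipped at
#'   the image border (flagged, never excluded).
#' @export
setClass("CellTerritorySet",
  representation(
    territories   = "list",
    coverCount    = "matrix",
    cellIds       = "integer",
    ringRadiusPx  = "numeric",
    nucleusArea   = "integer",
    centroidRow   = "numeric",
    centroidCol   = "numeric",
    touchesBorder = "logical"
  )
)

setValidity("CellTerritorySet", function(object) {
  if (length(object@territories) != length(object@cellIds)) {
    return("'territories' and 'cellIds' must have equal length")
  }
  cc <- object@coverCount
  if (length(object@territories) > 0L) {
    tab <- tabulate(unlist(object@territories, use.names = FALSE),
                    nbins = length(cc))
    if (!identical(as.integer(tab), as.integer(cc))) {
      return("'coverCount' inconsistent with 'territories'")
    }
  } else if (any(cc != 0L)) {
    return("empty territory set must have an all-zero coverCount")
  }
  TRUE
})

#' K-means colour classification of an IHC tile
#'
#' Per-pixel colour-class labels (1..K), the class centroids in RGB space,
#' the identities of the calreticulin-positive (DAB) and background (white)
#' classes, and the resulting calreticulin-negative fraction: the fraction of
#' tissue (non-background) pixels that are not in the positive class.
#'
#' @slot classLabels integer matrix (rows x cols) of class indices in 1..K.
#' @slot centroids K x 3 numeric matrix of RGB centroids (0..255 scale).
#' @slot positiveClass index of the calreticulin-positive (DAB brown) class.
#' @slot backgroundClass index of the non-tissue (white) class.
#' @slot negativeFraction fraction of tissue pixels outside the positive
#'   class, in [0, 1].
#' @slot K number of clusters.
#' @slot tissuePixels,positivePixels pixel counts entering the fraction.
#' @export
setClass("IHCClassification",
  representation(
    classLabels      = "matrix",
    centroids        = "matrix",
    positiveClass    = "integer",
    backgroundClass  = "integer",
    negativeFraction = "numeric",
    K                = "integer",
    tissuePixels     = "integer",
    positivePixels   = "integer"
  )
)

setValidity("IHCClassification", function(object) {
  K <- object@K
  if (ncol(object@centroids) != 3L || nrow(object@centroids) != K) {
    return("'centroids' must be a K x 3 matrix")
  }
  l <- object@classLabels
  if (any(l < 1L) || any(l > K)) return("class labels must lie in 1..K")
  if (object@positiveClass == object@backgroundClass) {
    return("positive and background class must differ")
  }
  f <- object@negativeFraction
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    return("'negativeFraction' must lie in [0, 1]")
  }
  TRUE
})

#' Ground truth of a simulated PLA scene
#'
#' Carries every parameter used to render a two-channel PLA field, so that
#' each downstream stage (threshold, watershed, territories, per-cell sums)
#' has a known answer.
#'
#' @slot imageShape integer (rows, cols).
#' @slot pixelSizeUm micrometres per pixel.
#' @slot nuclei n x 3 matrix: centerRow, centerCol, radiusPx (1-based,
#'   pixel-centred coordinates).
#' @slot touchingPairs 2-column integer matrix of declared sub-diameter
#'   nucleus pairs (0-row matrix when none).
#' @slot perCellTotal integrated PLA intensity generated for each cell
#'   (counts, before noise).
#' @slot punctaPerCell,punctumSigmaPx punctum count per cell and Gaussian
#'   spot width.
#' @slot territoryRadiusPx radius (nucleus radius + ring) within which each
#'   cell's puncta were placed.
#' @slot backgroundLevel,noiseSd uniform background and additive Gaussian
#'   noise SD (counts).
#' @slot seed the seed the scene was generated from.
#' @export
setClass("PLASceneTruth",
  representation(
    imageShape        = "integer",
    pixelSizeUm       = "numeric",
    nuclei            = "matrix",
    touchingPairs     = "matrix",
    perCellTotal      = "numeric",
    punctaPerCell     = "integer",
    punctumSigmaPx    = "numeric",
    territoryRadiusPx = "numeric",
    backgroundLevel   = "numeric",
    noiseSd           = "numeric",
    seed              = "integer"
  )
)

#' Ground truth of a simulated IHC tile
#'
#' Class order is fixed: 1 = DAB brown (calreticulin-positive), 2 =
#' hematoxylin blue (negative tissue), 3 = white background (non-tissue),
#' 4 = intermediate. \code{positiveFractionTruth} is the DAB share of the
#' tissue (non-white) pixels, exactly as counted in \code{classMap}.
#'
#' @slot imageShape integer (rows, cols).
#' @slot classColors 4 x 3 RGB matrix (0..255) in the fixed class order.
#' @slot classMap integer matrix of per-pixel ground-truth classes (1..4).
#' @slot positiveFractionTruth (# class-1 pixels) / (# non-class-3 pixels).
#' @slot colorNoiseSd per-channel Gaussian noise SD.
#' @slot separable \code{TRUE} when all pairwise centroid distances exceed
#'   6 x colorNoiseSd (clustering recovery expected); \code{FALSE} flags the
#'   non-separable regime.
#' @slot seed generation seed.
#' @export
setClass("IHCSceneTruth",
  representation(
    imageShape            = "integer",
    classColors           = "matrix",
    classMap              = "matrix",
    positiveFractionTruth = "numeric",
    colorNoiseSd          = "numeric",
    separable             = "logical",
    seed                  = "integer"
  )
)

#' Result of a two-sample or contingency test
#'
#' @slot statistic the test statistic (U, D, or the odds-ratio-free table
#'   statistic \code{NA} for Fisher, whose p-value is the object of interest).
#' @slot pValue two-sided p-value in (0, 1].
#' @slot method human-readable description of the procedure used, including
#'   whether the exact or the approximate path was taken.
#' @slot nPerGroup integer sample sizes.
#' @export
setClass("TestResult",
  representation(
    statistic = "numeric",
    pValue    = "numeric",
    method    = "character",
    nPerGroup = "integer"
  )
)

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    return("p-value must lie in (0, 1]")
  }
  TRUE
})
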