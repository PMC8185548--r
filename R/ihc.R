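#' K-means colour clustering of IHC pixels
#'
#' Clusters the RGB pixels of a brightfield IHC tile into \code{K} colour
#' classes (default 4: DAB brown, hematoxylin blue, white background, and an
#' intermediate class) with Lloyd's algorithm started from k-means++ seeds.
#' Raw RGB coordinates are used directly — no optical-density transform.
#'
#' Centroids are fitted on a uniform random subsample of at most
#' \code{fitPixels} pixels (whole tiles give identical results in
#' expectation and the subsample is seed-reproducible), with
#' \code{restarts} k-means++ restarts keeping the lowest within-cluster sum
#' of squares; every pixel of the tile is then assigned to its nearest
#' centroid (Euclidean distance, ties to the lowest index).
#'
#' @param rgb rows x cols x 3 array, values in 0..255.
#' @param K number of clusters (>= 1); with fewer distinct colours than
#'   \code{K} the clustering is ill-posed and an error is raised.
#' @param seed integer seed controlling subsampling and initialisation.
#' @param restarts k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300; iterations
#'   run to an assignment fixed point, normally far fewer).
#' @param fitPixels centroid-fitting subsample cap (default 2e5).
#' @return list with \code{centroids} (K x 3 matrix) and \code{classLabels}
#'   (integer matrix of indices in 1..K).
#' @export
clusterPixels <- function(rgb, K = 4L, seed = 17L, restarts = 10L,
                          maxIter = 300L, fitPixels = 2e5) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  n <- prod(dim(rgb)[1:2])
  X <- cbind(as.numeric(rgb[, , 1]), as.numeric(rgb[, , 2]),
             as.numeric(rgb[, , 3]))
  if (nrow(unique(X)) < K) {
    stop(sprintf("image has fewer than K = %d distinct colours", K))
  }
  withSeed(seed, {
    fit <- if (n > fitPixels) X[sample.int(n, fitPixels), , drop = FALSE]
           else X
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeansppInit(fit, K)
      km <- suppressWarnings(
        stats::kmeans(fit, centers = init, iter.max = maxIter,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    cen <- unname(best$centers)
    lab <- nearestCentroid(X, cen)
    list(centroids = cen,
         classLabels = matrix(lab, dim(rgb)[1], dim(rgb)[2]))
  })
}

# k-means++ seeding: first centre uniform, then points with probability
# proportional to squared distance from the nearest chosen centre
kmeansppInit <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (K == 1L) return(centers)
  d2 <- colSums((t(X) - centers[1L, ])^2)
  for (k in 2:K) {
    i <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else {
      # all remaining points coincide with a centre; any point will do
      sample.int(n, 1L)
    }
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, colSums((t(X) - centers[k, ])^2))
  }
  centers
}

nearestCentroid <- function(X, centers) {
  d <- matrix(0, nrow(X), nrow(centers))
  for (k in seq_len(nrow(centers))) {
    d[, k] <- colSums((t(X) - centers[k, ])^2)
  }
  max.col(-d, ties.method = "first")
}

#' Identify the positive and background colour classes
#'
#' The background (non-tissue) class is the centroid with maximum luminance
#' (0.299 R + 0.587 G + 0.114 B): the white slide. The calreticulin-positive
#' class is the non-background centroid nearest (Euclidean, RGB) to a
#' configurable reference DAB colour — the hue of the chromogen varies
#' between stains, so the reference is a parameter, not a constant. Exact
#' ties resolve to the lowest index with a warning.
#'
#' @param centroids K x 3 RGB centroid matrix.
#' @param referencePositiveRGB reference DAB colour, default
#'   \code{c(120, 80, 45)}.
#' @return list with \code{positiveClass} and \code{backgroundClass}
#'   (integer indices into the centroid rows).
#' @export
identifyClasses <- function(centroids, referencePositiveRGB = c(120, 80, 45)) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 3L,
            nrow(centroids) >= 2L)
  lum <- centroids %*% c(0.299, 0.587, 0.114)
  if (sum(lum == max(lum)) > 1L) {
    warning("luminance tie between centroids; lowest index taken as background")
  }
  bg <- which.max(lum)
  d <- colSums((t(centroids) - referencePositiveRGB)^2)
  d[bg] <- Inf
  if (sum(d == min(d)) > 1L) {
    warning("distance tie to the reference colour; lowest index taken")
  }
  list(positiveClass = as.integer(which.min(d)),
       backgroundClass = as.integer(bg))
}

#' Fraction of calreticulin-negative tissue pixels
#'
#' Diffuse cytoplasmic calreticulin gives many contiguous positive pixels
#' and few negative ones; surface-restricted (ecto-)calreticulin gives the
#' opposite, so the negative fraction is a descriptor of calreticulin
#' location. The denominator is tissue pixels only (background excluded),
#' making the score independent of how much bare slide the tile contains.
#'
#' @param classLabels integer matrix of class indices.
#' @param positiveClass,backgroundClass class identities, e.g. from
#'   [identifyClasses()].
#' @return fraction in [0, 1]; errors when the tile has no tissue pixel.
#' @export
negativePixelFraction <- function(classLabels, positiveClass,
                                  backgroundClass) {
  tissue <- classLabels != backgroundClass
  nTissue <- sum(tissue)
  if (nTissue == 0L) stop("no tissue (non-background) pixels in the tile")
  sum(tissue & classLabels != positiveClass) / nTissue
}

#' Classify an IHC tile end to end
#'
#' Runs [clusterPixels()], [identifyClasses()] and
#' [negativePixelFraction()] and bundles the result.
#'
#' @inheritParams clusterPixels
#' @inheritParams identifyClasses
#' @return an \linkS4class{IHCClassification}.
#' @examples
#' tile <- simulateIHCScene(seed = 11, positiveFraction = 0.3)
#' cls <- classifyIHC(tile$rgb, seed = 11)
#' negativeFraction(cls)   # ~ 0.7
#' @export
classifyIHC <- function(rgb, K = 4L, seed = 17L,
                        referencePositiveRGB = c(120, 80, 45), ...) {
  cl <- clusterPixels(rgb, K = K, seed = seed, ...)
  id <- identifyClasses(cl$centroids, referencePositiveRGB)
  frac <- negativePixelFraction(cl$classLabels, id$positiveClass,
                                id$backgroundClass)
  lab <- cl$classLabels
  tissue <- as.integer(sum(lab != id$backgroundClass))
  pos <- as.integer(sum(lab == id$positiveClass))
  new("IHCClassification",
      classLabels = lab, centroids = cl$centroids,
      positiveClass = id$positiveClass, backgroundClass = id$backgroundClass,
      negativeFraction = frac, K = as.integer(K),
      tissuePixels = tissue, positivePixels = pos)
}

#' Compare negative fractions between two conditions
#'
#' Two-sided Mann-Whitney test on per-image negative fractions of two
#' groups (the comparison applied to IHC localization scores).
#'
#' @param fractionsA,fractionsB numeric vectors of per-image fractions.
#' @return a \linkS4class{TestResult}.
#' @export
compareConditions <- function(fractionsA, fractionsB) {
  mannWhitneyU(fractionsA, fractionsB)
}
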