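#' Run the per-cell PLA quantification pipeline end to end
#'
#' Composes the stages: nuclei segmentation on the Hoechst channel
#' (mean + k SD threshold, seeded watershed, size filter), territory
#' construction (nucleus + ring with even splitting of shared pixels),
#' background estimation, and per-cell background-corrected intensity
#' summation. When \code{outDir} is given, writes \code{cells.csv},
#' \code{nuclei.csv} and a reproducibility \code{manifest.json} naming
#' every input and parameter, so a rerun from the manifest is
#' byte-identical.
#'
#' @param hoechst Hoechst channel: a \linkS4class{ChannelImage} or a file
#'   path.
#' @param pla PLA channel: a \linkS4class{ChannelImage} or a file path.
#' @param pixelSizeUm pixel size override applied to both channels when
#'   reading from file.
#' @param segParams a [segmentationParams()] bundle.
#' @param ringRadiusPx,ringRadiusUm,preferPhysical ring geometry, see
#'   [buildTerritories()].
#' @param backgroundMethod,backgroundPercentile background estimator, see
#'   [estimateBackground()].
#' @param background explicit background value; overrides estimation.
#' @param outDir optional output directory.
#' @param verbose log stage scalars (threshold, n cells, background,
#'   overlap share) to the console.
#' @return list with \code{cells} (per-cell data.frame), \code{nuclei}
#'   (geometry table), \code{labelMap}, \code{territories},
#'   \code{threshold}, \code{background}, \code{manifest}.
#' @examples
#' sc <- simulatePLAScene(seed = 4, nNuclei = 3)
#' res <- runPLAPipeline(sc$hoechst, sc$pla, ringRadiusPx = 17)
#' res$cells$corrected_intensity
#' @export
runPLAPipeline <- function(hoechst, pla, pixelSizeUm = NULL,
                           segParams = segmentationParams(),
                           ringRadiusPx = 100, ringRadiusUm = 8.5,
                           preferPhysical = FALSE,
                           backgroundMethod = "median",
                           backgroundPercentile = 0.5,
                           background = NULL,
                           outDir = NULL, verbose = FALSE) {
  inputs <- list(
    hoechst = if (is.character(hoechst)) hoechst else "<in-memory>",
    pla = if (is.character(pla)) pla else "<in-memory>")
  if (is.character(hoechst)) {
    hoechst <- readChannelImage(hoechst, pixelSizeUm, "hoechst")
  }
  if (is.character(pla)) pla <- readChannelImage(pla, pixelSizeUm, "pla")
  if (!identical(dim(hoechst@pixels), dim(pla@pixels))) {
    stop("pla_quantification: Hoechst and PLA images differ in shape")
  }

  labels <- tryStage("nuclei_segmentation", segmentNuclei(hoechst, segParams))
  thr <- attr(labels, "threshold")
  if (verbose) {
    message(sprintf("[segment] threshold = %.4g, n_cells = %d",
                    thr, labels@nCells))
  }
  if (labels@nCells == 0L) {
    cells <- quantEmpty()
    territories <- NULL
    b <- NA_real_
  } else {
    territories <- tryStage("territories",
      buildTerritories(labels, ringRadiusPx = ringRadiusPx,
                       ringRadiusUm = ringRadiusUm,
                       pixelSizeUm = pixelSizeUm %||% hoechst@pixelSizeUm,
                       preferPhysical = preferPhysical))
    b <- if (!is.null(background)) background else {
      tryStage("background",
        estimateBackground(pla, territories, method = backgroundMethod,
                           percentile = backgroundPercentile))
    }
    cells <- tryStage("quantification", quantifyCells(pla, territories, b))
    if (verbose) {
      shared <- sum(territories@coverCount > 1L)
      covered <- sum(territories@coverCount > 0L)
      message(sprintf(
        "[quantify] background = %.4g, covered px = %d (%.1f%% shared)",
        b, covered, 100 * shared / max(covered, 1)))
    }
  }

  manifest <- list(
    tool = "cellquant", version = pkgVersion(), mode = "pla",
    inputs = inputs,
    parameters = list(
      pixelSizeUm = pixelSizeUm %||% hoechst@pixelSizeUm,
      thresholdK = segParams$thresholdK,
      minAreaPx = segParams$minAreaPx, maxAreaPx = segParams$maxAreaPx,
      minSeedDistPx = segParams$minSeedDistPx,
      fillHoles = segParams$fillHoles,
      ringRadiusPx = ringRadiusPx, ringRadiusUm = ringRadiusUm,
      preferPhysical = preferPhysical,
      backgroundMethod = if (is.null(background)) backgroundMethod
                         else "explicit",
      background = background),
    results = list(threshold = thr, nCells = labels@nCells,
                   background = b))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(outDir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(nucleiTable(labels), file.path(outDir, "nuclei.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(cells = cells, nuclei = nucleiTable(labels), labelMap = labels,
       territories = territories, threshold = thr, background = b,
       manifest = manifest)
}

quantEmpty <- function() {
  data.frame(cell_id = integer(0), centroid_row = numeric(0),
             centroid_col = numeric(0), nucleus_area_px = integer(0),
             territory_area_px = numeric(0), raw_intensity = numeric(0),
             corrected_intensity = numeric(0), background_b = numeric(0),
             touches_border = logical(0))
}

#' Run the IHC calreticulin-localization pipeline on one tile
#'
#' Clusters the tile's RGB pixels into K colour classes, identifies the
#' DAB-positive and white-background classes, and computes the
#' calreticulin-negative fraction of tissue pixels. When \code{outDir} is
#' given, writes \code{ihc.csv} and \code{manifest.json}.
#'
#' @param image RGB array (rows x cols x 3, 0..255) or a file path.
#' @param K number of colour classes (default 4).
#' @param seed clustering seed.
#' @param referencePositiveRGB reference DAB colour.
#' @param imageId identifier used in the output table.
#' @param outDir optional output directory.
#' @param verbose log the resulting scalars.
#' @return list with \code{classification}
#'   (\linkS4class{IHCClassification}), \code{table} (one-row data.frame),
#'   \code{manifest}.
#' @export
runIHCPipeline <- function(image, K = 4L, seed = 17L,
                           referencePositiveRGB = c(120, 80, 45),
                           imageId = "tile", outDir = NULL,
                           verbose = FALSE) {
  inputPath <- if (is.character(image)) image else "<in-memory>"
  if (is.character(image)) image <- readRGBImage(image)
  cls <- tryStage("ihc_classification",
    classifyIHC(image, K = K, seed = seed,
                referencePositiveRGB = referencePositiveRGB))
  cen <- cls@centroids
  tab <- data.frame(
    image_id = imageId, K = cls@K,
    t(stats::setNames(as.vector(t(cen)),
      paste0("centroid_", rep(seq_len(nrow(cen)), each = 3L), "_",
             rep(c("r", "g", "b"), nrow(cen))))),
    positive_class = cls@positiveClass,
    background_class = cls@backgroundClass,
    tissue_pixels = cls@tissuePixels,
    positive_pixels = cls@positivePixels,
    negative_fraction = cls@negativeFraction)
  if (verbose) {
    message(sprintf("[ihc] %s: negative fraction = %.4f (%d tissue px)",
                    imageId, cls@negativeFraction, cls@tissuePixels))
  }
  manifest <- list(
    tool = "cellquant", version = pkgVersion(), mode = "ihc",
    inputs = list(image = inputPath),
    parameters = list(K = K, seed = seed,
                      referencePositiveRGB = referencePositiveRGB),
    results = list(negativeFraction = cls@negativeFraction))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outDir, "ihc.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(classification = cls, table = tab, manifest = manifest)
}

tryStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

pkgVersion <- function() {
  as.character(utils::packageVersion("cellquant"))
}
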