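# Image readers/writers: TIFF via the tiff package (8/16-bit integer data,
# resolution tags), PNG via the png package (8-bit).

#' Read a single-channel image as a ChannelImage
#'
#' Supports 8- and 16-bit single-channel TIFF and 8-bit grayscale PNG.
#' Intensities are returned as raw integer counts (0..255 or 0..65535).
#' The physical pixel size is taken from the TIFF resolution tags when
#' present; an explicit \code{pixelSizeUm} always wins.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixelSizeUm optional pixel size override in micrometres.
#' @param channelName channel tag for the result.
#' @return a \linkS4class{ChannelImage}.
#' @export
readChannelImage <- function(path, pixelSizeUm = NULL,
                             channelName = "unnamed") {
  a <- readImageArray(path)
  if (length(dim(a$data)) == 3L && dim(a$data)[3] > 1L) {
    stop(sprintf("'%s' has %d channels; expected a single-channel image",
                 path, dim(a$data)[3]))
  }
  px <- if (length(dim(a$data)) == 3L) a$data[, , 1] else a$data
  size <- if (!is.null(pixelSizeUm)) pixelSizeUm
          else if (!is.null(a$pixelSizeUm)) a$pixelSizeUm else 1
  ChannelImage(px, pixelSizeUm = size, channelName = channelName)
}

#' Read an RGB image
#'
#' @param path file path (.tif/.tiff/.png), 8-bit, 3 channels (a 4th alpha
#'   channel is dropped).
#' @return rows x cols x 3 integer array on the 0..255 scale.
#' @export
readRGBImage <- function(path) {
  a <- readImageArray(path)
  d <- dim(a$data)
  if (length(d) != 3L || d[3] < 3L) {
    stop(sprintf("'%s' is not an RGB image (found %s)", path,
                 paste(d, collapse = " x ")))
  }
  out <- a$data[, , 1:3, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

readImageArray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && !all(bits %in% c(8L, 16L))) {
      stop(sprintf("'%s': unsupported bit depth %s (8/16-bit only)",
                   path, paste(unique(bits), collapse = ",")))
    }
    size <- NULL
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      perUm <- switch(as.character(unit %||% "inch"),
                      inch = xres / 25400, cm = xres / 1e4, xres / 1e4)
      if (perUm > 0) size <- 1 / perUm
    }
    data <- unclass(img)
    attributes(data) <- list(dim = dim(img))
    list(data = data, pixelSizeUm = size)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    list(data = round(img * 255), pixelSizeUm = NULL)
  } else {
    stop(sprintf("'%s': unsupported format '%s' (TIFF or PNG only)",
                 path, ext))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ChannelImage as a 16-bit TIFF
#'
#' Counts are rounded and stored directly on the 16-bit scale (values above
#' 65535 are clipped).
#'
#' @param img a \linkS4class{ChannelImage}.
#' @param path output path.
#' @export
writeChannelImage <- function(img, path) {
  stopifnot(is(img, "ChannelImage"))
  p <- round(pmin(pmax(img@pixels, 0), 65535)) / 65535
  tiff::writeTIFF(p, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an RGB array as an 8-bit PNG
#'
#' @param rgb rows x cols x 3 array on the 0..255 scale.
#' @param path output path.
#' @export
writeRGBImage <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 255) / 255, path)
  invisible(path)
}

#' Write a simulated PLA scene to disk with a ground-truth sidecar
#'
#' Emits \code{<basename>_hoechst.tif}, \code{<basename>_pla.tif} (16-bit)
#' and \code{<basename>_truth.json}.
#'
#' @param scene result of [simulatePLAScene()].
#' @param outDir output directory (created if needed).
#' @param basename file basename.
#' @return invisibly, the three paths written.
#' @export
writePLAScene <- function(scene, outDir, basename = "scene") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ph <- file.path(outDir, paste0(basename, "_hoechst.tif"))
  pp <- file.path(outDir, paste0(basename, "_pla.tif"))
  pj <- file.path(outDir, paste0(basename, "_truth.json"))
  writeChannelImage(scene$hoechst, ph)
  writeChannelImage(scene$pla, pp)
  t <- scene$truth
  jsonlite::write_json(list(
    imageShape = t@imageShape, pixelSizeUm = t@pixelSizeUm,
    nuclei = unname(apply(t@nuclei, 1L, as.list)),
    touchingPairs = unname(apply(t@touchingPairs, 1L, as.list)),
    perCellTotal = t@perCellTotal, punctaPerCell = t@punctaPerCell,
    punctumSigmaPx = t@punctumSigmaPx,
    territoryRadiusPx = t@territoryRadiusPx,
    backgroundLevel = t@backgroundLevel, noiseSd = t@noiseSd,
    seed = t@seed), pj, auto_unbox = TRUE, digits = NA)
  invisible(c(hoechst = ph, pla = pp, truth = pj))
}

#' Write a simulated IHC tile to disk with a ground-truth sidecar
#'
#' Emits \code{<basename>_ihc.png} (8-bit RGB) and
#' \code{<basename>_truth.json} (the class map is stored run-length
#' encoded column-major).
#'
#' @param scene result of [simulateIHCScene()].
#' @param outDir output directory.
#' @param basename file basename.
#' @return invisibly, the two paths written.
#' @export
writeIHCScene <- function(scene, outDir, basename = "tile") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pi_ <- file.path(outDir, paste0(basename, "_ihc.png"))
  pj <- file.path(outDir, paste0(basename, "_truth.json"))
  writeRGBImage(scene$rgb, pi_)
  t <- scene$truth
  rle_ <- rle(as.integer(t@classMap))
  jsonlite::write_json(list(
    imageShape = t@imageShape,
    classColors = unname(apply(t@classColors, 1L, as.list)),
    classMapRle = list(lengths = rle_$lengths, values = rle_$values),
    positiveFractionTruth = t@positiveFractionTruth,
    colorNoiseSd = t@colorNoiseSd, separable = t@separable,
    seed = t@seed), pj, auto_unbox = TRUE, digits = NA)
  invisible(c(rgb = pi_, truth = pj))
}
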