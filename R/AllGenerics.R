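#' @rdname ChannelImage
#' @param object,x a \code{cellquant} object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname ChannelImage
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname ChannelImage
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabelMap-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellTerritorySet-class
#' @export
setGeneric("territoryPixels", function(x) standardGeneric("territoryPixels"))

#' @rdname CellTerritorySet-class
#' @export
setGeneric("coverCount", function(x) standardGeneric("coverCount"))

#' @rdname CellTerritorySet-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname CellTerritorySet-class
#' @export
setGeneric("ringRadiusPx", function(x) standardGeneric("ringRadiusPx"))

#' @rdname CellTerritorySet-class
#' @export
setGeneric("coveredMask", function(x) standardGeneric("coveredMask"))

#' @rdname IHCClassification-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname IHCClassification-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname IHCClassification-class
#' @export
setGeneric("positiveClass", function(x) standardGeneric("positiveClass"))

#' @rdname IHCClassification-class
#' @export
setGeneric("backgroundClass", function(x) standardGeneric("backgroundClass"))

#' @rdname IHCClassification-class
#' @export
setGeneric("negativeFraction", function(x) standardGeneric("negativeFraction"))

#' @rdname TestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TestResult-class
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
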