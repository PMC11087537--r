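#' @include AllClasses.R
NULL

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @export
setGeneric("mapMeta", function(x) standardGeneric("mapMeta"))

#' @export
setGeneric("mapName", function(x) standardGeneric("mapName"))

#' @export
setGeneric("nativeResolution", function(x) standardGeneric("nativeResolution"))

#' @export
setGeneric("nominalYear", function(x) standardGeneric("nominalYear"))

#' @export
setGeneric("refPoints", function(x) standardGeneric("refPoints"))

#' @export
setGeneric("binarize", function(x, rule) standardGeneric("binarize"))

#' @export
setGeneric("resampleToGrid", function(x, target)
  standardGeneric("resampleToGrid"))

#' @export
setGeneric("clipToBoundary", function(x, boundary)
  standardGeneric("clipToBoundary"))

#' @export
setGeneric("mappedArea", function(x) standardGeneric("mappedArea"))

#' @export
setGeneric("summarizeDataset", function(x) standardGeneric("summarizeDataset"))

#' @export
setGeneric("evaluateMap", function(map, dataset, ...)
  standardGeneric("evaluateMap"))

#' @export
setGeneric("metricValue", function(x) standardGeneric("metricValue"))

#' @export
setGeneric("metricSE", function(x) standardGeneric("metricSE"))

#' @export
setGeneric("errorProportions", function(x) standardGeneric("errorProportions"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("areaWeightsOf", function(x) standardGeneric("areaWeightsOf"))
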