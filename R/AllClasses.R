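#' @import methods
NULL

#' GridSpec: a regular raster grid
#'
#' Describes a north-up regular grid of square pixels. Pixel (1,1) is the
#' upper-left cell. A cell's value applies to the whole cell; a point is
#' assigned to the cell whose half-open extent contains it
#' (`[left, right)` in x, `(top, bottom]` in y, i.e. left and bottom edges
#' inclusive).
#'
#' @slot xmin x coordinate of the grid's left edge (map units).
#' @slot ymax y coordinate of the grid's top edge (map units).
#' @slot pixel Pixel size (map units per pixel, square pixels).
#' @slot nrow,ncol Grid dimensions in pixels.
#' @slot crs Free-text coordinate reference system identifier.
#' @export
setClass("GridSpec",
  representation(xmin = "numeric", ymax = "numeric", pixel = "numeric",
                 nrow = "integer", ncol = "integer", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixel) != 1L || !is.finite(object@pixel) ||
        object@pixel <= 0) {
      msg <- c(msg, "pixel size must be a single positive number")
    }
    if (object@nrow < 1L || object@ncol < 1L) {
      msg <- c(msg, "grid must have at least one row and one column")
    }
    if (length(msg)) msg else TRUE
  })

#' MapMetadata: provenance of a map product
#'
#' @slot name Product identifier.
#' @slot nativeResolution Native resolution in meters per pixel.
#' @slot nominalYear Nominal year the map represents.
#' @export
setClass("MapMetadata",
  representation(name = "character", nativeResolution = "numeric",
                 nominalYear = "integer"),
  validity = function(object) {
    if (length(object@nativeResolution) == 1L &&
        object@nativeResolution <= 0) {
      "nativeResolution must be > 0"
    } else {
      TRUE
    }
  })

#' ClassRaster: a single-band raster of class codes or fractions
#'
#' Values are stored as a numeric matrix in row-major map order (row 1 is the
#' top of the map); `NA` marks nodata, and nodata pixels are excluded from all
#' statistics.
#'
#' @slot grid A [GridSpec-class].
#' @slot values Numeric matrix of dimension `nrow(grid) x ncol(grid)`.
#' @export
setClass("ClassRaster",
  representation(grid = "GridSpec", values = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (d[1L] != object@grid@nrow || d[2L] != object@grid@ncol) {
      "values matrix dimensions must match the grid"
    } else {
      TRUE
    }
  })

#' BinaryCropMap: a crop/non-crop raster
#'
#' A [ClassRaster-class] restricted to values {0, 1, NA} (non-crop, crop,
#' nodata), carrying product metadata. The common currency of the pipeline.
#'
#' @slot metadata A [MapMetadata-class].
#' @export
setClass("BinaryCropMap",
  contains = "ClassRaster",
  representation(metadata = "MapMetadata"),
  validity = function(object) {
    v <- object@values
    bad <- !is.na(v) & v != 0 & v != 1
    if (any(bad)) "values must be 0, 1 or NA" else TRUE
  })

#' ConsensusRaster: per-pixel crop vote counts
#'
#' Values count how many of `nMaps` binary maps vote crop at each pixel
#' (0..K); a pixel is nodata if any constituent map is nodata there.
#'
#' @slot nMaps Number of maps K that voted.
#' @export
setClass("ConsensusRaster",
  contains = "ClassRaster",
  representation(nMaps = "integer"),
  validity = function(object) {
    v <- object@values
    if (any(!is.na(v) & (v < 0 | v > object@nMaps))) {
      "vote counts must lie in [0, nMaps]"
    } else {
      TRUE
    }
  })

#' NDVICube: a raster time series of NDVI
#'
#' @slot grid A [GridSpec-class].
#' @slot values Numeric array `nrow x ncol x T` with values in [-1, 1].
#' @slot dates Integer time step labels (e.g. day of year), length T.
#' @export
setClass("NDVICube",
  representation(grid = "GridSpec", values = "array", dates = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L || d[1L] != object@grid@nrow ||
        d[2L] != object@grid@ncol) {
      msg <- c(msg, "values must be an nrow x ncol x T array on the grid")
    } else if (d[3L] != length(object@dates)) {
      msg <- c(msg, "length(dates) must equal the number of time steps")
    }
    v <- object@values
    if (any(!is.na(v) & (v < -1 | v > 1))) {
      msg <- c(msg, "NDVI values must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' CropClassRule: how to binarize a class raster
#'
#' Exactly one variant is active:
#' * `codeSet`: crop iff the class code is in a set (e.g. the GlobCover
#'   cropland class codes);
#' * `threshold`: crop iff value exceeds a cutoff (strict or not), the rule
#'   used for probability layers;
#' * `fractionRange`: crop iff a crop-area-fraction value lies in
#'   `[low, high]` (inclusive), the rule used for 0-100% fraction products;
#' * `modeCode`: crop iff the (already mode-composited) class label equals a
#'   crop code.
#'
#' @slot variant One of `"codeSet"`, `"threshold"`, `"fractionRange"`,
#'   `"modeCode"`.
#' @slot params Variant parameters (see constructors).
#' @export
setClass("CropClassRule",
  representation(variant = "character", params = "list"),
  validity = function(object) {
    ok <- object@variant %in%
      c("codeSet", "threshold", "fractionRange", "modeCode")
    if (!ok) {
      return("unknown rule variant")
    }
    if (object@variant == "fractionRange" &&
        object@params$low >= object@params$high) {
      return("fractionRange requires low < high")
    }
    TRUE
  })

#' ReferenceDataset: interpreter-labeled evaluation points
#'
#' Points are stored as a data.frame with columns `id`, `x`, `y`,
#' `label_1 .. label_L` (per-interpreter labels in {0,1}), `final_label`
#' (the unanimous label, `NA` where interpreters disagreed) and optionally
#' `truth` and `stratum`. Retained points (after the unanimity filter) are
#' exactly those with a defined `final_label`.
#'
#' @slot region Region name.
#' @slot year Reference year.
#' @slot points The point table.
#' @slot design Sampling design label (`"uniform"` or `"stratified"`).
#' @export
setClass("ReferenceDataset",
  representation(region = "character", year = "integer",
                 points = "data.frame", design = "character"),
  validity = function(object) {
    p <- object@points
    need <- c("id", "x", "y", "final_label")
    if (nrow(p) > 0L && !all(need %in% names(p))) {
      return(paste("points must have columns:", paste(need, collapse = ", ")))
    }
    labCols <- grep("^label_", names(p), value = TRUE)
    if (nrow(p) > 0L && length(labCols) < 2L) {
      return("every point needs at least two interpreter labels")
    }
    if (nrow(p) > 0L) {
      labs <- as.matrix(p[labCols])
      unan <- apply(labs, 1L, function(z) length(unique(z)) == 1L)
      defined <- !is.na(p$final_label)
      if (!identical(unname(unan), unname(defined))) {
        return("final_label must be defined exactly for unanimous points")
      }
    }
    TRUE
  })

#' ConfusionMatrix: sample counts of (map class, reference class)
#'
#' 2x2 integer counts with rows indexing the map class and columns the
#' reference class; class order is (non-crop, crop), so
#' `counts = rbind(c(TN, FN), c(FP, TP))`.
#'
#' @slot counts 2x2 matrix of non-negative counts.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix"),
  validity = function(object) {
    cts <- object@counts
    if (!all(dim(cts) == c(2L, 2L))) {
      return("counts must be a 2x2 matrix")
    }
    if (any(cts < 0) || any(cts != round(cts))) {
      return("counts must be non-negative integers")
    }
    TRUE
  })

#' MappedAreaSummary: mapped pixels per class
#' @slot nNeg,nPos Pixel counts mapped non-crop / crop (nodata excluded).
#' @export
setClass("MappedAreaSummary",
  representation(nNeg = "numeric", nPos = "numeric"),
  validity = function(object) {
    if (object@nNeg + object@nPos <= 0) "map has no usable pixels" else TRUE
  })

#' AreaWeights: proportion of mapped area per class
#' @slot w Length-2 vector (non-crop, crop) summing to 1.
#' @export
setClass("AreaWeights",
  representation(w = "numeric"),
  validity = function(object) {
    if (length(object@w) != 2L) {
      return("w must have length 2")
    }
    if (any(object@w < 0 | object@w > 1)) {
      return("weights must lie in [0, 1]")
    }
    if (abs(sum(object@w) - 1) > 1e-12) {
      return("weights must sum to 1")
    }
    TRUE
  })

#' PopulationErrorMatrix: area-proportion error matrix
#'
#' The sample confusion matrix re-expressed as proportions of total mapped
#' area: `p[i, j] = W_i * C[i, j] / C_i.`, so row sums equal the area weights
#' and the whole matrix sums to 1. The hub of all accuracy estimates.
#'
#' @slot p 2x2 matrix of area proportions.
#' @slot weights The area weights W used to build it.
#' @export
setClass("PopulationErrorMatrix",
  representation(p = "matrix", weights = "numeric"),
  validity = function(object) {
    p <- object@p
    if (!all(dim(p) == c(2L, 2L))) {
      return("p must be 2x2")
    }
    if (any(p < 0)) {
      return("proportions must be non-negative")
    }
    if (abs(sum(p) - 1) > 1e-12) {
      return("proportions must sum to 1")
    }
    if (any(abs(rowSums(p) - object@weights) > 1e-12)) {
      return("row sums must equal the area weights")
    }
    TRUE
  })

#' MetricEstimate: an accuracy metric with its standard error
#' @slot value Metric value in [0, 1].
#' @slot se Non-negative standard error.
#' @export
setClass("MetricEstimate",
  representation(value = "numeric", se = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@value < -1e-12 || object@value > 1 + 1e-12) {
      msg <- c(msg, "value must lie in [0, 1]")
    }
    if (object@se < 0) {
      msg <- c(msg, "se must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' MapEvaluation: the full accuracy report for one map x region
#'
#' @slot mapName,region Identifiers.
#' @slot oa,uaCrop,paCrop,f1Crop [MetricEstimate-class] for overall accuracy,
#'   user's accuracy (precision), producer's accuracy (recall) and F1 of the
#'   crop class.
#' @slot confusion The sample [ConfusionMatrix-class].
#' @slot weights The [AreaWeights-class] used.
#' @export
setClass("MapEvaluation",
  representation(mapName = "character", region = "character",
                 oa = "MetricEstimate", uaCrop = "MetricEstimate",
                 paCrop = "MetricEstimate", f1Crop = "MetricEstimate",
                 confusion = "ConfusionMatrix", weights = "AreaWeights"))

#' ProductSpec: parameters of one synthetic map product
#'
#' @slot name Product identifier.
#' @slot nativeResolution Native resolution (m/px); must nest with the truth
#'   grid (integer multiple either way) so resampling is exact.
#' @slot nominalYear Nominal map year.
#' @slot omissionRate Probability a true crop pixel is mapped non-crop.
#' @slot commissionRate Probability a true non-crop pixel is mapped crop.
#' @export
setClass("ProductSpec",
  representation(name = "character", nativeResolution = "numeric",
                 nominalYear = "integer", omissionRate = "numeric",
                 commissionRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nativeResolution <= 0) {
      msg <- c(msg, "nativeResolution must be > 0")
    }
    for (r in c(object@omissionRate, object@commissionRate)) {
      if (r < 0 || r > 1) msg <- c(msg, "error rates must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' SyntheticScenario: everything needed to simulate a study region
#'
#' @slot seed Master seed; identical seeds give bit-identical outputs.
#' @slot grid Common (truth) grid.
#' @slot cropFraction Target crop fraction, strictly in (0, 1).
#' @slot products List of [ProductSpec-class].
#' @slot nReferencePoints Reference sample size.
#' @slot interpretersPerPoint Number of interpreters labeling each point (>= 2).
#' @slot labelNoiseRate Per-interpreter mislabel probability, in [0, 0.5).
#' @slot smoothScale Landscape autocorrelation scale (pixels).
#' @slot ndviParams Named list: cropBaseline, cropAmplitude, noncropBaseline,
#'   noncropAmplitude, noiseSd, nTimesteps.
#' @slot regionName,referenceYear Labels for the simulated study.
#' @export
setClass("SyntheticScenario",
  representation(seed = "integer", grid = "GridSpec",
                 cropFraction = "numeric", products = "list",
                 nReferencePoints = "integer",
                 interpretersPerPoint = "integer",
                 labelNoiseRate = "numeric", smoothScale = "numeric",
                 ndviParams = "list", regionName = "character",
                 referenceYear = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@cropFraction <= 0 || object@cropFraction >= 1) {
      msg <- c(msg, "cropFraction must lie strictly in (0, 1)")
    }
    if (object@labelNoiseRate < 0 || object@labelNoiseRate >= 0.5) {
      msg <- c(msg, "labelNoiseRate must lie in [0, 0.5)")
    }
    if (object@interpretersPerPoint < 2L) {
      msg <- c(msg, "interpretersPerPoint must be >= 2")
    }
    if (object@nReferencePoints < 1L) {
      msg <- c(msg, "nReferencePoints must be >= 1")
    }
    if (!all(vapply(object@products, is, logical(1), "ProductSpec"))) {
      msg <- c(msg, "products must be a list of ProductSpec")
    }
    if (length(msg)) msg else TRUE
  })

#' RunConfig: declarative configuration of a full pipeline run
#'
#' Exactly one of `scenario` (synthetic inputs) or `inputs` (paths to on-disk
#' maps/boundary/reference files) is set.
#'
#' @slot scenario A [SyntheticScenario-class] or `NULL`.
#' @slot inputs Named list of file paths (`maps`, `metadata`, `boundary`,
#'   `points`), or empty.
#' @slot commonResolution Common grid resolution (map units/pixel).
#' @slot majorityThreshold Vote count needed for the ensemble to call crop;
#'   `NA` means strict majority (votes > K/2).
#' @slot varianceMode `"printed"` or `"standard"` (see [varianceUA()]).
#' @slot outputDir Output directory.
#' @slot seed Run seed.
#' @export
setClass("RunConfig",
  representation(scenario = "ANY", inputs = "list",
                 commonResolution = "numeric", majorityThreshold = "numeric",
                 varianceMode = "character", outputDir = "character",
                 seed = "integer"),
  validity = function(object) {
    hasScenario <- !is.null(object@scenario)
    hasInputs <- length(object@inputs) > 0L
    if (hasScenario == hasInputs) {
      return("exactly one of scenario or inputs must be set")
    }
    if (object@commonResolution <= 0) {
      return("commonResolution must be > 0")
    }
    if (!object@varianceMode %in% c("printed", "standard")) {
      return("varianceMode must be 'printed' or 'standard'")
    }
    TRUE
  })
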