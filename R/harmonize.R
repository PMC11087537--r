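#' @include AllClasses.R AllGenerics.R raster.R
NULL

#' Binarization rules
#'
#' Constructors for the [CropClassRule-class] variants used to reduce
#' heterogeneous land-cover products to crop/non-crop:
#' `codeSetRule()` marks crop where the class code is in `codes` (the rule
#' for categorical products such as GlobCover's cropland class list);
#' `thresholdRule()` marks crop where the value exceeds `cutoff`
#' (strictly, by default, as for probability layers binarized at > 0.5);
#' `fractionRangeRule()` marks crop where a crop-area-fraction value lies in
#' the inclusive range `[low, high]` (as for 5-95% fraction masks);
#' `modeCodeRule()` marks crop where a class label — typically a
#' [modeComposite()] of a time series — equals `cropCode`.
#'
#' @param codes Integer class codes counted as crop.
#' @param cutoff Numeric threshold.
#' @param strict Use strict `>` (default) rather than `>=`.
#' @param low,high Inclusive fraction bounds.
#' @param cropCode The class code meaning crop.
#' @return A [CropClassRule-class].
#' @name cropClassRules
NULL

#' @rdname cropClassRules
#' @export
codeSetRule <- function(codes) {
  new("CropClassRule", variant = "codeSet",
      params = list(codes = as.numeric(codes)))
}

#' @rdname cropClassRules
#' @export
thresholdRule <- function(cutoff, strict = TRUE) {
  new("CropClassRule", variant = "threshold",
      params = list(cutoff = as.numeric(cutoff), strict = isTRUE(strict)))
}

#' @rdname cropClassRules
#' @export
fractionRangeRule <- function(low, high) {
  new("CropClassRule", variant = "fractionRange",
      params = list(low = as.numeric(low), high = as.numeric(high)))
}

#' @rdname cropClassRules
#' @export
modeCodeRule <- function(cropCode) {
  new("CropClassRule", variant = "modeCode",
      params = list(cropCode = as.numeric(cropCode)))
}

#' Binarize a class raster into a crop/non-crop map
#'
#' Applies a [CropClassRule-class] pixelwise; nodata is preserved. Fraction
#' rules refuse rasters whose values fall outside [0, 100], and code rules
#' refuse non-integer rasters, so a rule cannot silently be applied to the
#' wrong kind of product.
#'
#' @param x A [ClassRaster-class] (or [BinaryCropMap-class], which passes
#'   through unchanged under a code rule).
#' @param rule A [CropClassRule-class].
#' @param metadata Optional [MapMetadata-class] for the result.
#' @return A [BinaryCropMap-class].
#' @export
setMethod("binarize", "ClassRaster", function(x, rule) {
  stopifnot(is(rule, "CropClassRule"))
  v <- x@values
  obs <- v[!is.na(v)]
  p <- rule@params
  out <- switch(rule@variant,
    codeSet = {
      if (any(obs != round(obs))) {
        stop("code-set rule applied to a non-integer raster")
      }
      ifelse(v %in% p$codes, 1, 0)
    },
    threshold = {
      if (p$strict) as.numeric(v > p$cutoff) else as.numeric(v >= p$cutoff)
    },
    fractionRange = {
      if (length(obs) && (min(obs) < 0 || max(obs) > 100)) {
        stop("fraction-range rule applied to values outside [0, 100]")
      }
      as.numeric(v >= p$low & v <= p$high)
    },
    modeCode = {
      if (any(obs != round(obs))) {
        stop("mode-code rule applied to a non-integer raster")
      }
      as.numeric(v == p$cropCode)
    })
  out <- matrix(out, nrow = x@grid@nrow, ncol = x@grid@ncol)
  out[is.na(v)] <- NA
  meta <- if (is(x, "BinaryCropMap")) x@metadata else
    mapMetadata("binarized", x@grid@pixel, 0L)
  binaryCropMap(x@grid, out, meta)
})

#' Per-pixel mode composite of a raster time series
#'
#' Reduces a stack of class rasters on one grid to the per-pixel most
#' frequent class, ignoring nodata; ties go to the lowest class code so the
#' result is deterministic and independent of stack order.
#'
#' @param stack Non-empty list of [ClassRaster-class] on a common grid.
#' @return A [ClassRaster-class].
#' @export
modeComposite <- function(stack) {
  if (length(stack) == 0L) stop("empty raster stack")
  stopifnot(all(vapply(stack, is, logical(1), "ClassRaster")))
  g <- stack[[1L]]@grid
  for (r in stack) {
    if (!sameGrid(r@grid, g)) stop("all rasters must share a grid")
  }
  arr <- vapply(stack, function(r) r@values, stack[[1L]]@values)
  dim(arr) <- c(g@nrow * g@ncol, length(stack))
  out <- apply(arr, 1L, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    tab <- table(z)
    best <- names(tab)[tab == max(tab)]
    min(as.numeric(best))
  })
  classRaster(g, matrix(out, nrow = g@nrow, ncol = g@ncol))
}

#' Resample a binary map onto a target grid
#'
#' Nearest-neighbor resampling by containing-cell lookup of each target cell
#' center; appropriate for categorical values, which must not be averaged.
#' Target cells whose centers fall outside the source extent (or on source
#' nodata) become nodata.
#'
#' @param x A [BinaryCropMap-class].
#' @param target A [GridSpec-class] overlapping the source extent.
#' @return A [BinaryCropMap-class] on `target`.
#' @export
setMethod("resampleToGrid", "BinaryCropMap", function(x, target) {
  stopifnot(is(target, "GridSpec"))
  if (sameGrid(x@grid, target)) return(x)
  se <- gridExtent(x@grid)
  te <- gridExtent(target)
  if (te["xmin"] >= se["xmax"] || te["xmax"] <= se["xmin"] ||
      te["ymin"] >= se["ymax"] || te["ymax"] <= se["ymin"]) {
    stop("target grid does not overlap the map extent")
  }
  cc <- cellCenters(target)
  px <- rep(cc$x, each = target@nrow)
  py <- rep(cc$y, times = target@ncol)
  vals <- extractAt(x, px, py)
  binaryCropMap(target, matrix(vals, nrow = target@nrow, ncol = target@ncol),
                x@metadata)
})

#' Clip a map to a region boundary
#'
#' Pixels whose centers fall outside the boundary polygon are set to nodata;
#' retained pixels are unchanged bit for bit. Cell centers exactly on the
#' boundary edge count as inside.
#'
#' @param x A [BinaryCropMap-class].
#' @param boundary Polygon (two-column vertex matrix, or list of rings).
#' @return A clipped [BinaryCropMap-class]. If the boundary misses the raster
#'   entirely the result is all nodata, with a warning.
#' @export
setMethod("clipToBoundary", "BinaryCropMap", function(x, boundary) {
  g <- x@grid
  cc <- cellCenters(g)
  px <- rep(cc$x, each = g@nrow)
  py <- rep(cc$y, times = g@ncol)
  keep <- pointInPolygon(px, py, boundary)
  v <- x@values
  v[matrix(!keep, nrow = g@nrow, ncol = g@ncol)] <- NA
  if (!any(keep)) {
    warning("boundary is disjoint from the raster; result is all nodata")
  }
  binaryCropMap(g, v, x@metadata)
})

#' Mapped area per class
#'
#' Counts the pixels mapped to each class, excluding nodata. These counts are
#' the area matrix A from which the area weights W = A / n are formed.
#'
#' @param x A [BinaryCropMap-class] with at least one non-nodata pixel.
#' @return A [MappedAreaSummary-class].
#' @export
setMethod("mappedArea", "BinaryCropMap", function(x) {
  v <- x@values
  nNeg <- sum(v == 0, na.rm = TRUE)
  nPos <- sum(v == 1, na.rm = TRUE)
  if (nNeg + nPos == 0) stop("map has no non-nodata pixels")
  new("MappedAreaSummary", nNeg = nNeg, nPos = nPos)
})

#' Area weights from mapped area
#'
#' @param area A [MappedAreaSummary-class].
#' @return An [AreaWeights-class] with `w = c(nNeg, nPos) / n`.
#' @export
areaWeights <- function(area) {
  stopifnot(is(area, "MappedAreaSummary"))
  n <- area@nNeg + area@nPos
  new("AreaWeights", w = c(area@nNeg, area@nPos) / n)
}

setMethod("show", "MappedAreaSummary", function(object) {
  cat(sprintf("MappedAreaSummary: %g non-crop + %g crop = %g pixels\n",
              object@nNeg, object@nPos, object@nNeg + object@nPos))
})

setMethod("show", "AreaWeights", function(object) {
  cat(sprintf("AreaWeights: W = [%.6g (non-crop), %.6g (crop)]\n",
              object@w[1L], object@w[2L]))
})
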