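#' @include AllClasses.R AllGenerics.R grid.R
NULL

#' Construct a ClassRaster
#'
#' @param grid A [GridSpec-class].
#' @param values Numeric matrix (`NA` = nodata), `nrow(grid) x ncol(grid)`.
#' @return A [ClassRaster-class].
#' @export
classRaster <- function(grid, values) {
  new("ClassRaster", grid = grid, values = matrix(as.numeric(values),
                                                  nrow = grid@nrow,
                                                  ncol = grid@ncol))
}

#' Construct MapMetadata
#' @param name Product name.
#' @param nativeResolution Native resolution (m/px).
#' @param nominalYear Nominal year.
#' @export
mapMetadata <- function(name, nativeResolution, nominalYear) {
  new("MapMetadata", name = name,
      nativeResolution = as.numeric(nativeResolution),
      nominalYear = as.integer(nominalYear))
}

#' Construct a BinaryCropMap
#'
#' @param grid A [GridSpec-class].
#' @param values Matrix of 0/1/`NA`.
#' @param metadata A [MapMetadata-class]; defaults to anonymous metadata at
#'   the grid's own resolution.
#' @return A [BinaryCropMap-class].
#' @export
binaryCropMap <- function(grid, values,
                          metadata = mapMetadata("unnamed", grid@pixel, 0L)) {
  new("BinaryCropMap", grid = grid,
      values = matrix(as.numeric(values), nrow = grid@nrow,
                      ncol = grid@ncol),
      metadata = metadata)
}

#' @describeIn gridSpec Grid of a raster.
#' @export
setMethod("gridSpec", "ClassRaster", function(x) x@grid)
#' @export
setMethod("gridSpec", "NDVICube", function(x) x@grid)
#' @export
setMethod("rasterValues", "ClassRaster", function(x) x@values)
#' @export
setMethod("rasterValues", "NDVICube", function(x) x@values)
#' @export
setMethod("mapMeta", "BinaryCropMap", function(x) x@metadata)
#' @export
setMethod("mapName", "BinaryCropMap", function(x) x@metadata@name)
#' @export
setMethod("mapName", "MapMetadata", function(x) x@name)
#' @export
setMethod("nativeResolution", "BinaryCropMap",
          function(x) x@metadata@nativeResolution)
#' @export
setMethod("nativeResolution", "MapMetadata", function(x) x@nativeResolution)
#' @export
setMethod("nominalYear", "BinaryCropMap", function(x) x@metadata@nominalYear)
#' @export
setMethod("nominalYear", "MapMetadata", function(x) x@nominalYear)

#' Extract raster values at point locations
#'
#' Nearest-cell (containing-cell) lookup under the half-open cell convention.
#'
#' @param x A [ClassRaster-class].
#' @param px,py Point coordinates.
#' @return Numeric vector of cell values; `NA` for points off the grid or on
#'   nodata cells.
#' @export
extractAt <- function(x, px, py) {
  stopifnot(is(x, "ClassRaster"))
  idx <- cellIndex(x@grid, px, py)
  out <- rep(NA_real_, length(px))
  ok <- !is.na(idx$row)
  out[ok] <- x@values[cbind(idx$row[ok], idx$col[ok])]
  out
}

setMethod("show", "ClassRaster", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d pixels @ %g units/px, %d nodata\n",
              class(object), nrow(v), ncol(v), object@grid@pixel,
              sum(is.na(v))))
  vals <- v[!is.na(v)]
  if (length(vals)) {
    cat(sprintf("  values: min %g, max %g, mean %.4g\n",
                min(vals), max(vals), mean(vals)))
  }
})

setMethod("show", "BinaryCropMap", function(object) {
  v <- object@values
  cat(sprintf("BinaryCropMap '%s' (%g m/px native, year %d)\n",
              object@metadata@name, object@metadata@nativeResolution,
              object@metadata@nominalYear))
  cat(sprintf("  grid: %d x %d @ %g units/px; crop %d, non-crop %d, nodata %d\n",
              nrow(v), ncol(v), object@grid@pixel,
              sum(v == 1, na.rm = TRUE), sum(v == 0, na.rm = TRUE),
              sum(is.na(v))))
})

setMethod("show", "ConsensusRaster", function(object) {
  v <- object@values
  cat(sprintf("ConsensusRaster of %d maps: %d x %d pixels, %d nodata\n",
              object@nMaps, nrow(v), ncol(v), sum(is.na(v))))
  cat("  vote counts:\n")
  print(table(factor(v[!is.na(v)], levels = 0:object@nMaps)))
})
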