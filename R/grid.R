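#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GridSpec
#'
#' @param xmin,ymax Coordinates of the grid's upper-left corner (map units).
#' @param pixel Pixel size (map units per pixel).
#' @param nrow,ncol Grid dimensions in pixels.
#' @param crs Coordinate reference system label; synthetic scenarios use a
#'   local planar system (`"local"`).
#' @return A [GridSpec-class].
#' @examples
#' gridSpec10 <- gridSpecNew(0, 1000, pixel = 10, nrow = 100, ncol = 100)
#' @export
gridSpecNew <- function(xmin, ymax, pixel, nrow, ncol, crs = "local") {
  new("GridSpec", xmin = as.numeric(xmin), ymax = as.numeric(ymax),
      pixel = as.numeric(pixel), nrow = as.integer(nrow),
      ncol = as.integer(ncol), crs = crs)
}

#' Cell centers of a grid
#'
#' @param grid A [GridSpec-class].
#' @return List with numeric vectors `x` (length ncol, left to right) and `y`
#'   (length nrow, top to bottom).
#' @export
cellCenters <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  list(
    x = grid@xmin + (seq_len(grid@ncol) - 0.5) * grid@pixel,
    y = grid@ymax - (seq_len(grid@nrow) - 0.5) * grid@pixel
  )
}

#' Locate the grid cell containing each point
#'
#' Cells are half-open: a point on a cell's left or bottom edge belongs to
#' that cell, a point on its right or top edge belongs to the neighbor.
#'
#' @param grid A [GridSpec-class].
#' @param x,y Point coordinates.
#' @return Data frame with integer columns `row`, `col` (`NA` outside the
#'   grid).
#' @export
cellIndex <- function(grid, x, y) {
  stopifnot(is(grid, "GridSpec"), length(x) == length(y))
  col <- floor((x - grid@xmin) / grid@pixel) + 1
  row <- ceiling((grid@ymax - y) / grid@pixel)
  ok <- row >= 1 & row <= grid@nrow & col >= 1 & col <= grid@ncol
  row[!ok] <- NA
  col[!ok] <- NA
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid extent
#' @param grid A [GridSpec-class].
#' @return Named vector xmin, xmax, ymin, ymax.
#' @export
gridExtent <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  c(xmin = grid@xmin, xmax = grid@xmin + grid@ncol * grid@pixel,
    ymin = grid@ymax - grid@nrow * grid@pixel, ymax = grid@ymax)
}

#' Do two grids describe the same pixels?
#' @keywords internal
sameGrid <- function(a, b, tol = 1e-9) {
  is(a, "GridSpec") && is(b, "GridSpec") &&
    abs(a@xmin - b@xmin) <= tol && abs(a@ymax - b@ymax) <= tol &&
    abs(a@pixel - b@pixel) <= tol && a@nrow == b@nrow && a@ncol == b@ncol
}

setMethod("show", "GridSpec", function(object) {
  ext <- gridExtent(object)
  cat(sprintf("GridSpec: %d x %d pixels @ %g units/px (%s)\n",
              object@nrow, object@ncol, object@pixel, object@crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
})
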