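#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so every generator in the package is a
#' pure function of its inputs and seed without touching global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Test whether points fall inside a polygon
#'
#' Even-odd (ray crossing) containment test for one or more polygon rings.
#' Points lying exactly on a ring edge or vertex count as inside; this makes
#' the rule deterministic for cell centers that coincide with boundary
#' segments.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param polygon A two-column matrix of ring vertices (closed or open), or a
#'   list of such matrices for multi-ring polygons (even-odd rule, so interior
#'   rings act as holes).
#' @return Logical vector, `TRUE` where the point is inside or on the edge.
#' @export
pointInPolygon <- function(x, y, polygon) {
  rings <- if (is.list(polygon)) polygon else list(polygon)
  stopifnot(length(x) == length(y))
  inside <- rep(FALSE, length(x))
  onEdge <- rep(FALSE, length(x))
  for (ring in rings) {
    ring <- as.matrix(ring)
    stopifnot(ncol(ring) == 2L, nrow(ring) >= 3L)
    vx <- ring[, 1L]
    vy <- ring[, 2L]
    n <- length(vx)
    if (vx[1L] == vx[n] && vy[1L] == vy[n]) {
      vx <- vx[-n]
      vy <- vy[-n]
      n <- n - 1L
    }
    j <- n
    for (i in seq_len(n)) {
      xi <- vx[i]; yi <- vy[i]
      xj <- vx[j]; yj <- vy[j]
      cross <- (x - xi) * (yj - yi) - (y - yi) * (xj - xi)
      onSeg <- cross == 0 &
        x >= pmin(xi, xj) & x <= pmax(xi, xj) &
        y >= pmin(yi, yj) & y <= pmax(yi, yj)
      onEdge <- onEdge | onSeg
      spans <- (yi > y) != (yj > y)
      if (any(spans)) {
        xAt <- xi + (y - yi) * (xj - xi) / (yj - yi)
        crossesRay <- spans & (x < xAt)
        inside <- xor(inside, crossesRay)
      }
      j <- i
    }
  }
  inside | onEdge
}

#' Polygon area (shoelace, even-odd over rings)
#' @keywords internal
polygonArea <- function(polygon) {
  rings <- if (is.list(polygon)) polygon else list(polygon)
  sum(vapply(rings, function(r) {
    r <- as.matrix(r)
    abs(pracma::polyarea(r[, 1L], r[, 2L]))
  }, numeric(1)))
}

#' Bounding box of a polygon
#' @keywords internal
polygonBBox <- function(polygon) {
  rings <- if (is.list(polygon)) polygon else list(polygon)
  allv <- do.call(rbind, lapply(rings, as.matrix))
  c(xmin = min(allv[, 1L]), xmax = max(allv[, 1L]),
    ymin = min(allv[, 2L]), ymax = max(allv[, 2L]))
}

# format a value +/- sd pair at 2 decimals, Table-1 display style
formatPlusMinus <- function(value, sd) {
  sprintf("%.2f ± %.2f", value, sd)
}
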