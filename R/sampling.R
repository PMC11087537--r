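#' @include AllClasses.R AllGenerics.R raster.R
NULL

#' Draw a uniform random point sample within a boundary
#'
#' Rejection sampling from the boundary's bounding box, so points are
#' uniform over the polygon's area. Points on the polygon edge count as
#' inside.
#'
#' @param boundary Polygon (two-column vertex matrix or list of rings).
#' @param n Number of points (>= 1).
#' @param seed Seed.
#' @return Data frame with columns `x`, `y` of exactly `n` points.
#' @export
sampleUniform <- function(boundary, n, seed) {
  stopifnot(n >= 1)
  if (polygonArea(boundary) <= 0) stop("boundary has zero area")
  bb <- polygonBBox(boundary)
  withSeed(seed, {
    xs <- numeric(0)
    ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 100L)
      cx <- stats::runif(m, bb["xmin"], bb["xmax"])
      cy <- stats::runif(m, bb["ymin"], bb["ymax"])
      keep <- pointInPolygon(cx, cy, boundary)
      xs <- c(xs, cx[keep])
      ys <- c(ys, cy[keep])
    }
    data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
  })
}

#' Draw a stratified random point sample
#'
#' Strata are left-open right-closed intervals `(a, b]` over a covariate
#' raster (e.g. mean annual NDVI), matching the convention of NDVI-defined
#' strata; every non-empty stratum receives exactly `nPerStratum` points
#' (equal allocation). Candidate cells are those whose centers fall inside
#' the boundary; sampled points are placed uniformly within their cell so
#' each point's covariate value is the cell's value.
#'
#' @param covariate A [ClassRaster-class] covering the boundary.
#' @param boundary Polygon.
#' @param strata List of numeric `c(low, high)` pairs, disjoint.
#' @param nPerStratum Points per stratum.
#' @param seed Seed.
#' @return Data frame with columns `x`, `y`, `stratum` (index into `strata`)
#'   and `covariate`. Strata with no eligible pixels get zero points, with a
#'   warning.
#' @export
sampleStratified <- function(covariate, boundary, strata, nPerStratum, seed) {
  stopifnot(is(covariate, "ClassRaster"), nPerStratum >= 1)
  lows <- vapply(strata, `[`, numeric(1), 1L)
  highs <- vapply(strata, `[`, numeric(1), 2L)
  ord <- order(lows)
  if (any(highs[ord][-length(ord)] > lows[ord][-1L] + 1e-12)) {
    stop("strata intervals must be disjoint")
  }
  g <- covariate@grid
  cc <- cellCenters(g)
  px <- rep(cc$x, each = g@nrow)
  py <- rep(cc$y, times = g@ncol)
  vals <- as.vector(covariate@values)
  eligible <- !is.na(vals) & pointInPolygon(px, py, boundary)
  withSeed(seed, {
    out <- list()
    for (s in seq_along(strata)) {
      inStratum <- eligible & vals > lows[s] & vals <= highs[s]
      idx <- which(inStratum)
      if (!length(idx)) {
        warning(sprintf("stratum %d (%g, %g] has no eligible pixels", s,
                        lows[s], highs[s]))
        next
      }
      pick <- idx[sample.int(length(idx), nPerStratum, replace = TRUE)]
      jx <- stats::runif(nPerStratum, -0.5, 0.5) * g@pixel
      jy <- stats::runif(nPerStratum, -0.5, 0.5) * g@pixel
      out[[s]] <- data.frame(x = px[pick] + jx, y = py[pick] + jy,
                             stratum = s, covariate = vals[pick])
    }
    do.call(rbind, out)
  })
}

#' Assemble a reference point table
#'
#' @param locations Data frame with columns `x`, `y` (and optionally
#'   `stratum`).
#' @param labels Integer matrix of interpreter labels, one row per point,
#'   >= 2 columns (see [generateInterpreterLabels()]).
#' @param truth Optional vector of true labels.
#' @return Data frame with `id`, `x`, `y`, `label_*` columns (and `truth`,
#'   `stratum` when supplied), ready for [consensusFilter()].
#' @export
referencePoints <- function(locations, labels, truth = NULL) {
  labels <- as.matrix(labels)
  stopifnot(nrow(locations) == nrow(labels), ncol(labels) >= 2L)
  colnames(labels) <- paste0("label_", seq_len(ncol(labels)))
  out <- data.frame(id = seq_len(nrow(locations)),
                    x = locations$x, y = locations$y)
  out <- cbind(out, as.data.frame(labels))
  if (!is.null(truth)) out$truth <- as.integer(truth)
  if (!is.null(locations$stratum)) out$stratum <- locations$stratum
  out
}

#' Unanimity (consensus) filter over interpreter labels
#'
#' Retains exactly the points whose interpreters all agree and assigns the
#' common label as `final_label`; disagreeing points are discarded. With
#' per-interpreter error rate e and L interpreters, the expected retention
#' fraction is `(1-e)^L + e^L`.
#'
#' @param points Point table from [referencePoints()].
#' @param region,year,design Dataset metadata.
#' @return A [ReferenceDataset-class] containing only retained points. An
#'   empty input yields an empty dataset with a warning.
#' @export
consensusFilter <- function(points, region = "region", year = 0L,
                            design = "uniform") {
  labCols <- grep("^label_", names(points), value = TRUE)
  if (nrow(points) == 0L) {
    warning("no input points; returning an empty dataset")
    points$final_label <- integer(0)
    return(new("ReferenceDataset", region = region, year = as.integer(year),
               points = points, design = design))
  }
  stopifnot(length(labCols) >= 2L)
  labs <- as.matrix(points[labCols])
  unanimous <- rowSums(labs == labs[, 1L]) == ncol(labs)
  points$final_label <- ifelse(unanimous, labs[, 1L], NA_integer_)
  retained <- points[unanimous, , drop = FALSE]
  new("ReferenceDataset", region = region, year = as.integer(year),
      points = retained, design = design)
}

#' Construct a ReferenceDataset directly from final labels
#'
#' Convenience for datasets known only through their summary counts (each
#' point duplicated across two concordant pseudo-interpreters).
#'
#' @param locations Data frame with `x`, `y`.
#' @param finalLabels Vector in {0, 1}.
#' @param region,year,design Metadata.
#' @return A [ReferenceDataset-class].
#' @export
referenceDatasetFromLabels <- function(locations, finalLabels,
                                       region = "region", year = 0L,
                                       design = "uniform") {
  labs <- cbind(label_1 = as.integer(finalLabels),
                label_2 = as.integer(finalLabels))
  consensusFilter(referencePoints(locations, labs), region = region,
                  year = year, design = design)
}

#' @export
setMethod("refPoints", "ReferenceDataset", function(x) x@points)

#' Summarize a reference dataset (sample-count table row)
#'
#' @param x A non-empty [ReferenceDataset-class].
#' @return One-row data frame: `region`, `total`, `crop`, `noncrop`,
#'   `crop_pct` (crop percentage, one decimal).
#' @export
setMethod("summarizeDataset", "ReferenceDataset", function(x) {
  p <- x@points
  if (nrow(p) == 0L) stop("empty dataset")
  total <- nrow(p)
  crop <- sum(p$final_label == 1L)
  data.frame(region = x@region, total = total, crop = crop,
             noncrop = total - crop,
             crop_pct = round(100 * crop / total, 1L))
})

setMethod("show", "ReferenceDataset", function(object) {
  p <- object@points
  cat(sprintf("ReferenceDataset '%s' (%d, %s design): %d retained points\n",
              object@region, object@year, object@design, nrow(p)))
  if (nrow(p)) {
    cat(sprintf("  crop %d, non-crop %d (crop %.1f%%)\n",
                sum(p$final_label == 1L), sum(p$final_label == 0L),
                100 * mean(p$final_label == 1L)))
  }
})
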