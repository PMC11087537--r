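#' @include AllClasses.R AllGenerics.R accuracy.R
NULL

#' Mean and SD of each metric across maps
#'
#' The per-region synthesis: each metric averaged across all evaluated maps,
#' with the sample standard deviation (divisor n - 1).
#'
#' @param evals List of >= 2 [MapEvaluation-class].
#' @return Data frame with columns `metric`, `mean`, `sd` and a 2-decimal
#'   `display` ("mean ± SD").
#' @export
countryMeanMetrics <- function(evals) {
  if (length(evals) < 2L) stop("at least two evaluations are required")
  vals <- t(vapply(evals, metricValue, numeric(4)))
  mns <- colMeans(vals)
  sds <- apply(vals, 2L, stats::sd)
  data.frame(metric = c("overall_accuracy", "users_accuracy",
                        "producers_accuracy", "f1"),
             mean = unname(mns), sd = unname(sds),
             display = formatPlusMinus(mns, sds))
}

#' Temporal mismatch between a map and the reference data
#'
#' @param mapYear Nominal map year(s); for multi-year products pass all
#'   nominal years and the closest is used.
#' @param referenceYear Reference data year.
#' @return Non-negative integer `|mapYear - referenceYear|` (minimum over
#'   supplied years).
#' @export
temporalMismatch <- function(mapYear, referenceYear) {
  min(abs(as.integer(mapYear) - as.integer(referenceYear)))
}

#' Pearson correlation of a metric with a map covariate
#'
#' Correlates per-map mean metric values with either native resolution or
#' temporal mismatch, optionally excluding named maps first (the device used
#' to probe the influence of coarse or dated outliers). A zero-variance
#' vector makes the correlation undefined; this is reported as `NA` with a
#' reason, never silently as 0.
#'
#' @param metricValues Named numeric vector of per-map metric values.
#' @param metadata List of [MapMetadata-class], one per map (matched by
#'   name).
#' @param covariate `"resolution"` or `"temporal_mismatch"`.
#' @param referenceYear Needed for temporal mismatch.
#' @param exclude Character vector of map names to drop before correlating.
#' @return List with `r` (Pearson coefficient or `NA`), `covariate`,
#'   `excluded`, `n` and `reason` (non-`NULL` only when `r` is undefined).
#' @export
metricCovariateCorrelation <- function(metricValues, metadata,
                                       covariate = c("resolution",
                                                     "temporal_mismatch"),
                                       referenceYear = NULL,
                                       exclude = character()) {
  covariate <- match.arg(covariate)
  metaNames <- vapply(metadata, mapName, character(1))
  keep <- setdiff(intersect(names(metricValues), metaNames), exclude)
  if (length(keep) < 3L) {
    stop("at least three maps are required after exclusions")
  }
  meta <- metadata[match(keep, metaNames)]
  x <- switch(covariate,
    resolution = vapply(meta, nativeResolution, numeric(1)),
    temporal_mismatch = {
      if (is.null(referenceYear)) {
        stop("referenceYear is required for temporal mismatch")
      }
      vapply(meta, function(m)
        temporalMismatch(nominalYear(m), referenceYear), numeric(1))
    })
  y <- unname(metricValues[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, covariate = covariate, excluded = exclude,
                n = length(keep),
                reason = "zero variance in metric or covariate"))
  }
  list(r = stats::cor(x, y), covariate = covariate, excluded = exclude,
       n = length(keep), reason = NULL)
}

#' Zonal mean NDVI time series under a crop mask
#'
#' For each time step, averages NDVI over pixels where the mask is crop and
#' (optionally) the cell center lies inside the region boundary — the
#' standard way a crop mask conditions a downstream vegetation-index
#' analysis. The mask must already be on the cube's grid (resample it first
#' if it is not).
#'
#' @param cube An [NDVICube-class].
#' @param mask A [BinaryCropMap-class] on the same grid.
#' @param region Optional polygon boundary.
#' @return Data frame with columns `date` and `mean_ndvi`. If the mask
#'   selects no pixels the series is all `NA`, with a warning.
#' @export
maskedNdviSeries <- function(cube, mask, region = NULL) {
  stopifnot(is(cube, "NDVICube"), is(mask, "BinaryCropMap"))
  if (!sameGrid(cube@grid, mask@grid)) {
    stop("mask must be on the NDVI cube's grid; resample it first")
  }
  sel <- !is.na(mask@values) & mask@values == 1
  if (!is.null(region)) {
    g <- cube@grid
    cc <- cellCenters(g)
    px <- rep(cc$x, each = g@nrow)
    py <- rep(cc$y, times = g@ncol)
    inRegion <- matrix(pointInPolygon(px, py, region),
                       nrow = g@nrow, ncol = g@ncol)
    sel <- sel & inRegion
  }
  nT <- dim(cube@values)[3L]
  if (!any(sel)) {
    warning("mask selects no pixels; series is undefined")
    return(data.frame(date = cube@dates, mean_ndvi = rep(NA_real_, nT)))
  }
  m <- vapply(seq_len(nT), function(k) {
    band <- cube@values[, , k]
    mean(band[sel], na.rm = TRUE)
  }, numeric(1))
  data.frame(date = cube@dates, mean_ndvi = m)
}
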