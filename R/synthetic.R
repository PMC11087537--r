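#' @include AllClasses.R AllGenerics.R raster.R harmonize.R
NULL

#' Construct a ProductSpec
#'
#' @param name Product identifier.
#' @param nativeResolution Native resolution (m/px).
#' @param nominalYear Nominal map year.
#' @param omissionRate Probability a true crop pixel is mapped non-crop.
#' @param commissionRate Probability a true non-crop pixel is mapped crop.
#' @return A [ProductSpec-class].
#' @export
productSpec <- function(name, nativeResolution, nominalYear,
                        omissionRate, commissionRate) {
  new("ProductSpec", name = name,
      nativeResolution = as.numeric(nativeResolution),
      nominalYear = as.integer(nominalYear),
      omissionRate = as.numeric(omissionRate),
      commissionRate = as.numeric(commissionRate))
}

#' Default NDVI simulation parameters
#'
#' A 16-day-cadence annual series (23 steps): crop pixels peak near NDVI 0.7
#' in season and drop near 0.15 off season (high seasonal amplitude), while
#' natural vegetation varies much less around a similar baseline, matching
#' the contrast that NDVI-stratified sampling exploits.
#'
#' @return Named list of parameters.
#' @export
defaultNdviParams <- function() {
  list(cropBaseline = 0.35, cropAmplitude = 0.35,
       noncropBaseline = 0.30, noncropAmplitude = 0.08,
       noiseSd = 0.05, nTimesteps = 23L)
}

#' Construct a SyntheticScenario
#'
#' Bundles every knob of the synthetic study region: the truth grid and crop
#' fraction, the degraded products to derive from it, the reference sampling
#' effort and interpreter behavior, and NDVI dynamics. Identical scenarios
#' (including `seed`) generate bit-identical data.
#'
#' @param seed Master seed.
#' @param grid Truth [GridSpec-class].
#' @param cropFraction Target crop fraction in (0, 1).
#' @param products List of [ProductSpec-class].
#' @param nReferencePoints Number of reference points to sample.
#' @param interpretersPerPoint Interpreters labeling each point (>= 2).
#' @param labelNoiseRate Per-interpreter mislabel probability in [0, 0.5).
#' @param smoothScale Landscape autocorrelation scale in pixels.
#' @param ndviParams See [defaultNdviParams()].
#' @param regionName,referenceYear Labels.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(seed, grid, cropFraction = 0.3,
                              products = list(),
                              nReferencePoints = 500L,
                              interpretersPerPoint = 2L,
                              labelNoiseRate = 0.1,
                              smoothScale = 5,
                              ndviParams = defaultNdviParams(),
                              regionName = "synthetic",
                              referenceYear = 2019L) {
  new("SyntheticScenario", seed = as.integer(seed), grid = grid,
      cropFraction = as.numeric(cropFraction), products = products,
      nReferencePoints = as.integer(nReferencePoints),
      interpretersPerPoint = as.integer(interpretersPerPoint),
      labelNoiseRate = as.numeric(labelNoiseRate),
      smoothScale = as.numeric(smoothScale), ndviParams = ndviParams,
      regionName = regionName, referenceYear = as.integer(referenceYear))
}

# Gaussian smoothing matrix for one axis, rows renormalized at the edges
smoothingMatrix <- function(n, scale) {
  if (scale <= 0) return(diag(n))
  idx <- seq_len(n)
  S <- exp(-0.5 * (outer(idx, idx, "-") / scale)^2)
  S / rowSums(S)
}

#' Generate a spatially autocorrelated binary truth landscape
#'
#' White noise is smoothed with a separable Gaussian kernel (scale
#' `smoothScale` pixels), then thresholded at the empirical
#' `1 - cropFraction` quantile, producing contiguous field-like patches whose
#' realized crop fraction matches the target to within one pixel's worth of
#' the quantile rounding.
#'
#' @param scenario A [SyntheticScenario-class].
#' @return A [BinaryCropMap-class] named `"truth"` on the scenario grid.
#' @export
generateTrueLandscape <- function(scenario) {
  stopifnot(is(scenario, "SyntheticScenario"))
  g <- scenario@grid
  if (g@nrow < 1L || g@ncol < 1L) stop("degenerate grid")
  withSeed(scenario@seed, {
    z <- matrix(stats::rnorm(g@nrow * g@ncol), nrow = g@nrow)
    sm <- smoothingMatrix(g@nrow, scenario@smoothScale) %*% z %*%
      t(smoothingMatrix(g@ncol, scenario@smoothScale))
    thr <- stats::quantile(sm, probs = 1 - scenario@cropFraction,
                           names = FALSE)
    binaryCropMap(g, (sm > thr) * 1,
                  mapMetadata("truth", g@pixel,
                              scenario@referenceYear))
  })
}

#' Derive a degraded product map from the truth
#'
#' If the product's native resolution is coarser than the truth grid, the
#' truth is first aggregated to native resolution by majority vote of the
#' covered truth pixels (ties to non-crop, the dominant-class semantics of
#' coarse products); if finer, truth pixels are replicated. Each crop pixel
#' is then flipped to non-crop independently with probability
#' `omissionRate`, and each non-crop pixel to crop with probability
#' `commissionRate`, so the product's true producer's accuracy is
#' `1 - omissionRate` and its user's accuracy has the closed form
#' `(1-o) f / ((1-o) f + c (1-f))` for crop fraction `f`.
#'
#' @param truth A [BinaryCropMap-class] (no nodata).
#' @param spec A [ProductSpec-class]; its resolution must nest with the truth
#'   grid.
#' @param seed Seed for the error process.
#' @return A [BinaryCropMap-class] at the product's native resolution.
#' @export
degradeMap <- function(truth, spec, seed) {
  stopifnot(is(truth, "BinaryCropMap"), is(spec, "ProductSpec"))
  g <- truth@grid
  ratio <- spec@nativeResolution / g@pixel
  v <- truth@values
  if (abs(ratio - round(ratio)) < 1e-9 && round(ratio) >= 1) {
    r <- as.integer(round(ratio))
    if (r > 1L) {
      if (g@nrow %% r != 0L || g@ncol %% r != 0L) {
        stop("truth grid dimensions must be divisible by the aggregation factor")
      }
      nr <- g@nrow %/% r
      nc <- g@ncol %/% r
      # block sums via index arithmetic; crop iff strictly more than half
      rowBlk <- (seq_len(g@nrow) - 1L) %/% r + 1L
      colBlk <- (seq_len(g@ncol) - 1L) %/% r + 1L
      sums <- rowsum(t(rowsum(v, rowBlk)), colBlk)  # nc x nr
      v <- t(sums) > (r * r / 2)
      v <- v * 1
      g <- gridSpecNew(g@xmin, g@ymax, spec@nativeResolution, nr, nc, g@crs)
    }
  } else {
    inv <- g@pixel / spec@nativeResolution
    if (abs(inv - round(inv)) > 1e-9) {
      stop("native resolution must be an integer multiple of the truth grid (or vice versa)")
    }
    r <- as.integer(round(inv))
    v <- v[rep(seq_len(g@nrow), each = r), rep(seq_len(g@ncol), each = r)]
    g <- gridSpecNew(g@xmin, g@ymax, spec@nativeResolution,
                     g@nrow * r, g@ncol * r, g@crs)
  }
  withSeed(seed, {
    u <- matrix(stats::runif(length(v)), nrow = nrow(v))
    out <- v
    out[v == 1 & u < spec@omissionRate] <- 0
    out[v == 0 & u < spec@commissionRate] <- 1
    binaryCropMap(g, out,
                  mapMetadata(spec@name, spec@nativeResolution,
                              spec@nominalYear))
  })
}

#' Simulate interpreter labels for reference points
#'
#' Each of `nInterpreters` labels independently equals the true label with
#' probability `1 - noiseRate`. Rates of 0.5 or more are rejected: labels
#' would carry no information.
#'
#' @param truthLabels Vector of true labels in {0, 1}.
#' @param nInterpreters Number of interpreters (>= 2).
#' @param noiseRate Mislabel probability in [0, 0.5).
#' @param seed Seed.
#' @return Integer matrix `length(truthLabels) x nInterpreters`.
#' @export
generateInterpreterLabels <- function(truthLabels, nInterpreters, noiseRate,
                                      seed) {
  if (noiseRate >= 0.5 || noiseRate < 0) {
    stop("noiseRate must lie in [0, 0.5): labels would be uninformative")
  }
  if (nInterpreters < 2L) stop("at least two interpreters are required")
  n <- length(truthLabels)
  withSeed(seed, {
    flips <- matrix(stats::runif(n * nInterpreters) < noiseRate, nrow = n)
    labs <- matrix(rep(as.integer(truthLabels), nInterpreters), nrow = n)
    labs[flips] <- 1L - labs[flips]
    colnames(labs) <- paste0("label_", seq_len(nInterpreters))
    labs
  })
}

#' Simulate an NDVI time series cube
#'
#' Every pixel follows a seasonal sinusoid
#' `baseline + amplitude * sin(2 pi (t-1) / T)` with class-specific baseline
#' and amplitude (crop amplitude larger, so crop pixels green up and senesce
#' more strongly), plus Gaussian noise of the stated sd; the result is
#' clamped to the NDVI domain [-1, 1].
#'
#' @param scenario A [SyntheticScenario-class].
#' @param truth Optional precomputed truth map (regenerated from the
#'   scenario when omitted).
#' @return An [NDVICube-class] with `nTimesteps` bands; `dates` are days of
#'   year at a 16-day cadence.
#' @export
generateNdviCube <- function(scenario, truth = generateTrueLandscape(scenario)) {
  stopifnot(is(scenario, "SyntheticScenario"), is(truth, "BinaryCropMap"))
  p <- scenario@ndviParams
  g <- truth@grid
  tt <- seq_len(p$nTimesteps)
  isCrop <- truth@values == 1
  base <- ifelse(isCrop, p$cropBaseline, p$noncropBaseline)
  amp <- ifelse(isCrop, p$cropAmplitude, p$noncropAmplitude)
  arr <- array(NA_real_, dim = c(g@nrow, g@ncol, p$nTimesteps))
  withSeed(scenario@seed + 1L, {
    for (k in tt) {
      season <- sin(2 * pi * (k - 1) / p$nTimesteps)
      band <- base + amp * season
      if (p$noiseSd > 0) {
        band <- band + matrix(stats::rnorm(length(band), sd = p$noiseSd),
                              nrow = g@nrow)
      }
      arr[, , k] <- pmin(1, pmax(-1, band))
    }
  })
  new("NDVICube", grid = g, values = arr,
      dates = as.integer(round((tt - 1) * 365 / p$nTimesteps) + 1L))
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario '%s' (seed %d)\n", object@regionName,
              object@seed))
  cat(sprintf("  grid %d x %d @ %g units/px; crop fraction %.3f\n",
              object@grid@nrow, object@grid@ncol, object@grid@pixel,
              object@cropFraction))
  cat(sprintf("  %d products; %d reference points; %d interpreters @ noise %.3f\n",
              length(object@products), object@nReferencePoints,
              object@interpretersPerPoint, object@labelNoiseRate))
})

setMethod("show", "ProductSpec", function(object) {
  cat(sprintf("ProductSpec '%s': %g m/px, year %d, omission %.3f, commission %.3f\n",
              object@name, object@nativeResolution, object@nominalYear,
              object@omissionRate, object@commissionRate))
})
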