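#' @include AllClasses.R AllGenerics.R raster.R harmonize.R sampling.R
NULL

# class order everywhere: 1 = non-crop, 2 = crop

#' Construct a ConfusionMatrix from counts
#'
#' @param tn,fn,fp,tp Sample counts (map class in rows, reference class in
#'   columns: row 1 = map non-crop `[TN, FN]`, row 2 = map crop `[FP, TP]`).
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(tn, fn, fp, tp) {
  m <- rbind(c(tn, fn), c(fp, tp))
  dimnames(m) <- list(map = c("noncrop", "crop"),
                      reference = c("noncrop", "crop"))
  new("ConfusionMatrix", counts = m)
}

#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

#' Tabulate map predictions against reference labels
#'
#' Looks up the map value at each retained reference point (containing-cell
#' rule) and cross-tabulates it with the point's final label. Points falling
#' on nodata pixels or off the grid are dropped, with a message reporting
#' how many.
#'
#' @param dataset A [ReferenceDataset-class] (unanimity-filtered).
#' @param map A [BinaryCropMap-class].
#' @return A [ConfusionMatrix-class].
#' @export
buildConfusion <- function(dataset, map) {
  stopifnot(is(dataset, "ReferenceDataset"), is(map, "BinaryCropMap"))
  p <- dataset@points
  if (nrow(p) == 0L) stop("no usable reference points")
  pred <- extractAt(map, p$x, p$y)
  usable <- !is.na(pred)
  if (sum(!usable) > 0L) {
    message(sprintf("dropping %d point(s) on nodata or outside the map",
                    sum(!usable)))
  }
  if (!any(usable)) stop("no usable reference points")
  pred <- pred[usable]
  ref <- p$final_label[usable]
  confusionMatrix(tn = sum(pred == 0 & ref == 0),
                  fn = sum(pred == 0 & ref == 1),
                  fp = sum(pred == 1 & ref == 0),
                  tp = sum(pred == 1 & ref == 1))
}

#' Population error matrix from sample counts and area weights
#'
#' Re-expresses the sample confusion matrix as proportions of total mapped
#' area: `p[i, j] = W_i * C[i, j] / C_i.` (rows normalized by their sample
#' totals, then scaled by the mapped-area weight of the row's class). Rows
#' with zero area weight are zero; a mapped class with positive weight but
#' no samples is an error, since its conditional error rates are
#' unobserved.
#'
#' @param C A [ConfusionMatrix-class].
#' @param W An [AreaWeights-class].
#' @return A [PopulationErrorMatrix-class]; row sums equal `W` exactly and
#'   the entries sum to 1.
#' @export
populationMatrix <- function(C, W) {
  stopifnot(is(C, "ConfusionMatrix"), is(W, "AreaWeights"))
  cts <- C@counts
  rowTot <- rowSums(cts)
  p <- matrix(0, 2L, 2L, dimnames = dimnames(cts))
  for (i in 1:2) {
    if (W@w[i] > 0) {
      if (rowTot[i] == 0) {
        stop(sprintf(
          "map class %d has positive area weight but no reference samples", i))
      }
      p[i, ] <- W@w[i] * cts[i, ] / rowTot[i]
    }
  }
  new("PopulationErrorMatrix", p = p, weights = W@w)
}

#' @export
setMethod("errorProportions", "PopulationErrorMatrix", function(x) x@p)
#' @export
setMethod("areaWeightsOf", "PopulationErrorMatrix",
          function(x) new("AreaWeights", w = x@weights))

#' Overall accuracy from the population error matrix
#'
#' @param E A [PopulationErrorMatrix-class].
#' @return The trace of E: the area-weighted proportion correctly mapped.
#' @export
overallAccuracy <- function(E) {
  stopifnot(is(E, "PopulationErrorMatrix"))
  sum(diag(E@p))
}

#' User's accuracy (precision) of a class
#'
#' `P_i = p_ii / p_i.` (diagonal over the row sum of the population error
#' matrix): the probability that a pixel mapped as class i truly is class i.
#' A class that is never mapped (`p_i. = 0`) has user's accuracy 0 by
#' convention.
#'
#' @param E A [PopulationErrorMatrix-class].
#' @param classIndex 1 = non-crop, 2 = crop (default).
#' @export
usersAccuracy <- function(E, classIndex = 2L) {
  stopifnot(is(E, "PopulationErrorMatrix"))
  den <- sum(E@p[classIndex, ])
  if (den == 0) 0 else E@p[classIndex, classIndex] / den
}

#' Producer's accuracy (recall) of a class
#'
#' `R_j = p_jj / p_.j` (diagonal over the column sum): the probability that
#' a pixel truly of class j is mapped as class j. A class absent from the
#' reference (`p_.j = 0`) has producer's accuracy 0 by convention.
#'
#' @inheritParams usersAccuracy
#' @export
producersAccuracy <- function(E, classIndex = 2L) {
  stopifnot(is(E, "PopulationErrorMatrix"))
  den <- sum(E@p[, classIndex])
  if (den == 0) 0 else E@p[classIndex, classIndex] / den
}

# row-conditional correct proportion P_i = C_ii / C_i. (equals UA of class i)
rowConditional <- function(cts, i) {
  tot <- sum(cts[i, ])
  if (tot == 0) 0 else cts[i, i] / tot
}

# one stratum's contribution W_i^2 P_i (1-P_i) / (C_i. - 1); 0 with a warning
# when the variance is undefined (fewer than 2 samples in a weighted stratum)
strataVarTerm <- function(cts, w, i) {
  if (w[i] == 0) return(0)
  tot <- sum(cts[i, ])
  if (tot < 2) {
    warning(sprintf(
      "variance undefined for map class %d (fewer than 2 samples); reporting 0",
      i))
    return(0)
  }
  Pi <- rowConditional(cts, i)
  w[i]^2 * Pi * (1 - Pi) / (tot - 1)
}

#' Variance of overall accuracy
#'
#' Stratified (by map class) variance of the area-weighted overall accuracy:
#' `V(OA) = sum_i W_i^2 P_i (1 - P_i) / (C_i. - 1)` with
#' `P_i = C_ii / C_i.`.
#'
#' @param C A [ConfusionMatrix-class].
#' @param W An [AreaWeights-class].
#' @return The variance estimate (SE is its square root).
#' @export
varianceOA <- function(C, W) {
  stopifnot(is(C, "ConfusionMatrix"), is(W, "AreaWeights"))
  sum(vapply(1:2, function(i) strataVarTerm(C@counts, W@w, i), numeric(1)))
}

#' Variance of user's accuracy
#'
#' As printed, `V(P_i) = W_i^2 P_i (1 - P_i) / (C_i. - 1)` — note the
#' `W_i^2` factor. `mode = "standard"` drops that factor, giving the
#' binomial form `P_i (1 - P_i) / (C_i. - 1)` conventional for a
#' within-stratum conditional proportion.
#'
#' @inheritParams varianceOA
#' @param classIndex 1 = non-crop, 2 = crop.
#' @param mode `"printed"` (default) or `"standard"`.
#' @export
varianceUA <- function(C, W, classIndex = 2L,
                       mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  stopifnot(is(C, "ConfusionMatrix"), is(W, "AreaWeights"))
  v <- strataVarTerm(C@counts, W@w, classIndex)
  if (mode == "standard" && W@w[classIndex] > 0) {
    v <- v / W@w[classIndex]^2
  }
  v
}

#' Variance of producer's accuracy
#'
#' `V(R_j) = (1 / Nhat_.j^2) * [ A_j^2 (1-R_j)^2 P_j (1-P_j) / (C_j. - 1)
#'   + R_j^2 * sum_{i != j} A_i^2 (C_ij/C_i.)(1 - C_ij/C_i.) / (C_i. - 1) ]`
#' where `Nhat_.j = sum_i (A_i / C_i.) C_ij` is the estimated number of
#' pixels of reference class j.
#'
#' @inheritParams varianceUA
#' @param A A [MappedAreaSummary-class] (pixel counts per mapped class).
#' @export
variancePA <- function(C, W, A, classIndex = 2L) {
  stopifnot(is(C, "ConfusionMatrix"), is(W, "AreaWeights"),
            is(A, "MappedAreaSummary"))
  cts <- unname(C@counts)
  area <- c(A@nNeg, A@nPos)
  rowTot <- rowSums(cts)
  j <- classIndex
  Nhat <- sum(ifelse(rowTot > 0, area * cts[, j] / pmax(rowTot, 1), 0))
  if (Nhat == 0) return(0)
  E <- populationMatrix(C, W)
  Rj <- producersAccuracy(E, j)
  Pj <- rowConditional(cts, j)
  term1 <- 0
  if (area[j] > 0) {
    if (rowTot[j] < 2) {
      warning(sprintf(
        "variance undefined for map class %d (fewer than 2 samples); reporting 0",
        j))
    } else {
      term1 <- area[j]^2 * (1 - Rj)^2 * Pj * (1 - Pj) / (rowTot[j] - 1)
    }
  }
  term2 <- 0
  for (i in 1:2) {
    if (i == j || rowTot[i] < 2 || area[i] == 0) next
    q <- cts[i, j] / rowTot[i]
    term2 <- term2 + area[i]^2 * q * (1 - q) / (rowTot[i] - 1)
  }
  (term1 + Rj^2 * term2) / Nhat^2
}

#' Construct a MetricEstimate
#' @param value Metric value.
#' @param se Standard error.
#' @export
metricEstimate <- function(value, se = 0) {
  new("MetricEstimate", value = as.numeric(value), se = as.numeric(se))
}

#' @export
setMethod("metricValue", "MetricEstimate", function(x) x@value)
#' @export
setMethod("metricSE", "MetricEstimate", function(x) x@se)
#' @export
setMethod("metricValue", "MapEvaluation", function(x) {
  c(oa = x@oa@value, ua = x@uaCrop@value, pa = x@paCrop@value,
    f1 = x@f1Crop@value)
})
#' @export
setMethod("metricSE", "MapEvaluation", function(x) {
  c(oa = x@oa@se, ua = x@uaCrop@se, pa = x@paCrop@se, f1 = x@f1Crop@se)
})

#' F1 score with propagated standard error
#'
#' `F1 = 2PR / (P + R)`. Because the uncertainties of the numerator and
#' denominator are not independent, relative errors add rather than adding
#' in quadrature, giving
#' `dF1 = 2 (R dP + P dR) / (P + R) + 2PR (dP + dR) / (P + R)^2`.
#' When `P + R = 0` both the score and its error are 0.
#'
#' @param P,R [MetricEstimate-class] for precision (user's accuracy) and
#'   recall (producer's accuracy).
#' @return A [MetricEstimate-class] for F1.
#' @export
f1WithError <- function(P, R) {
  stopifnot(is(P, "MetricEstimate"), is(R, "MetricEstimate"))
  if (P@se < 0 || R@se < 0) stop("standard errors must be non-negative")
  p <- P@value; r <- R@value
  dp <- P@se; dr <- R@se
  if (p + r == 0) return(metricEstimate(0, 0))
  f1 <- 2 * p * r / (p + r)
  df1 <- 2 * (r * dp + p * dr) / (p + r) +
    2 * p * r * (dp + dr) / (p + r)^2
  metricEstimate(f1, df1)
}

#' Evaluate a map against a reference dataset
#'
#' The full design-based chain: cross-tabulate predictions and labels, form
#' the area weights from the mapped area, build the population error matrix,
#' and report overall accuracy, crop user's/producer's accuracy and F1, each
#' with its standard error.
#'
#' @param map A [BinaryCropMap-class].
#' @param dataset A [ReferenceDataset-class].
#' @param varianceMode `"printed"` or `"standard"`, see [varianceUA()].
#' @return A [MapEvaluation-class].
#' @export
setMethod("evaluateMap", signature(map = "BinaryCropMap",
                                   dataset = "ReferenceDataset"),
          function(map, dataset, varianceMode = c("printed", "standard")) {
  varianceMode <- match.arg(varianceMode)
  C <- buildConfusion(dataset, map)
  A <- mappedArea(map)
  W <- areaWeights(A)
  E <- populationMatrix(C, W)
  oa <- metricEstimate(overallAccuracy(E), sqrt(varianceOA(C, W)))
  ua <- metricEstimate(usersAccuracy(E, 2L),
                       sqrt(varianceUA(C, W, 2L, varianceMode)))
  pa <- metricEstimate(producersAccuracy(E, 2L),
                       sqrt(variancePA(C, W, A, 2L)))
  f1 <- f1WithError(ua, pa)
  new("MapEvaluation", mapName = mapName(map), region = dataset@region,
      oa = oa, uaCrop = ua, paCrop = pa, f1Crop = f1,
      confusion = C, weights = W)
})

#' Turn evaluations into a long-format metric table
#'
#' @param evals List of [MapEvaluation-class].
#' @return Data frame with columns `map`, `region`, `metric`, `value`, `se`
#'   (full precision) plus `display` (value ± se at 2 decimals).
#' @export
evaluationTable <- function(evals) {
  rows <- lapply(evals, function(e) {
    vals <- metricValue(e)
    ses <- metricSE(e)
    data.frame(map = e@mapName, region = e@region,
               metric = c("overall_accuracy", "users_accuracy",
                          "producers_accuracy", "f1"),
               value = unname(vals), se = unname(ses),
               display = formatPlusMinus(vals, ses))
  })
  do.call(rbind, rows)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = map, cols = reference):\n")
  print(object@counts)
})

setMethod("show", "PopulationErrorMatrix", function(object) {
  cat("PopulationErrorMatrix (area proportions):\n")
  print(round(object@p, 6))
  cat(sprintf("  row sums (= area weights): %.6g, %.6g\n",
              object@weights[1L], object@weights[2L]))
})

setMethod("show", "MetricEstimate", function(object) {
  cat(formatPlusMinus(object@value, object@se), "\n")
})

setMethod("show", "MapEvaluation", function(object) {
  cat(sprintf("MapEvaluation: '%s' on '%s'\n", object@mapName,
              object@region))
  v <- metricValue(object)
  s <- metricSE(object)
  for (k in seq_along(v)) {
    cat(sprintf("  %-4s %s\n", names(v)[k], formatPlusMinus(v[k], s[k])))
  }
})
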