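test_that("buildConfusion tallies map-vs-reference pairs", {
  g <- localGrid(10L)
  set.seed(1)
  # all-non-crop map against 10 crop + 437 non-crop reference points
  mali <- countDataset(g, 10L, 437L, region = "Mali")
  m0 <- binaryCropMap(g, matrix(0, 10L, 10L))
  C <- buildConfusion(mali, m0)
  expect_equal(confusionCounts(C),
               confusionMatrix(437, 10, 0, 0)@counts)
  # a map that equals the reference at every point has no off-diagonals
  tr <- randomBinaryMap(g, 0.4)
  loc <- data.frame(x = runif(50, 0, 10 - 1e-9), y = runif(50, 1e-9, 10 - 1e-9))
  labels <- extractAt(tr, loc$x, loc$y)
  ds <- referenceDatasetFromLabels(loc, labels)
  Cp <- confusionCounts(buildConfusion(ds, tr))
  expect_equal(Cp[1L, 2L] + Cp[2L, 1L], 0)
  # points on nodata are dropped with a message
  vNA <- rasterValues(tr)
  vNA[, 1:3] <- NA
  trNA <- binaryCropMap(g, vNA)
  expect_message(buildConfusion(ds, trNA), "dropping")
  # random instances match a per-point tally oracle
  for (k in 1:10) {
    mm <- randomBinaryMap(g, runif(1, 0.2, 0.8), pNodata = 0.1)
    dd <- countDataset(g, sample(5:20, 1), sample(5:20, 1))
    got <- suppressMessages(confusionCounts(buildConfusion(dd, mm)))
    expect_equal(unname(got), oracleConfusion(refPoints(dd), mm))
  }
})

test_that("population matrix is the row-normalized, area-weighted C", {
  C <- confusionMatrix(90, 10, 20, 80)
  W <- new("AreaWeights", w = c(0.7, 0.3))
  E <- populationMatrix(C, W)
  expect_equal(errorProportions(E),
               matrix(c(0.63, 0.06, 0.07, 0.24), 2L,
                      dimnames = dimnames(errorProportions(E))))
  # W equal to sample row proportions reduces E to C / sum(C)
  Ws <- new("AreaWeights", w = c(0.5, 0.5))
  Es <- populationMatrix(C, Ws)
  expect_equal(unname(errorProportions(Es)),
               unname(confusionCounts(C)) / 200)
  # Mali worked example: W = [1, 0]
  Em <- populationMatrix(confusionMatrix(437, 10, 0, 0),
                         new("AreaWeights", w = c(1, 0)))
  expect_equal(unname(errorProportions(Em)),
               rbind(c(437 / 447, 10 / 447), c(0, 0)))
  # a mapped class with no samples cannot be normalized
  expect_error(populationMatrix(confusionMatrix(90, 10, 0, 0), W),
               "no reference samples")
})

test_that("population matrix identities hold on random instances", {
  set.seed(14)
  for (k in 1:50) {
    cts <- matrix(rpois(4, 30) + 1, 2L)
    w2 <- runif(1)
    W <- new("AreaWeights", w = c(1 - w2, w2))
    C <- confusionMatrix(cts[1, 1], cts[1, 2], cts[2, 1], cts[2, 2])
    E <- populationMatrix(C, W)
    p <- errorProportions(E)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(p)), W@w, tolerance = 1e-12)
    expect_equal(unname(p), oraclePopulationMatrix(confusionCounts(C), W@w))
  }
})

test_that("OA, UA, PA follow the population error matrix", {
  C <- confusionMatrix(90, 10, 20, 80)
  W <- new("AreaWeights", w = c(0.7, 0.3))
  E <- populationMatrix(C, W)
  expect_equal(overallAccuracy(E), 0.87)
  expect_equal(usersAccuracy(E, 2L), 0.8)
  expect_equal(producersAccuracy(E, 2L), 0.24 / 0.31)
  # perfect diagonal
  Ed <- populationMatrix(confusionMatrix(50, 0, 0, 50),
                         new("AreaWeights", w = c(0.5, 0.5)))
  expect_equal(overallAccuracy(Ed), 1)
  expect_equal(usersAccuracy(Ed, 1L), 1)
  expect_equal(producersAccuracy(Ed, 2L), 1)
  # Mali degenerate case: crop never mapped and OA = 437/447
  Em <- populationMatrix(confusionMatrix(437, 10, 0, 0),
                         new("AreaWeights", w = c(1, 0)))
  expect_equal(round(overallAccuracy(Em), 2), 0.98)
  expect_equal(usersAccuracy(Em, 2L), 0)
  expect_equal(producersAccuracy(Em, 2L), 0)
})

test_that("variance estimators reproduce the printed formulas", {
  # independent re-implementation of the printed estimators, from scratch
  C <- confusionMatrix(90, 10, 20, 80)
  W <- new("AreaWeights", w = c(0.7, 0.3))
  n <- 10000
  A <- new("MappedAreaSummary", nNeg = 0.7 * n, nPos = 0.3 * n)
  P1 <- 90 / 100; P2 <- 80 / 100
  vOA <- 0.7^2 * P1 * (1 - P1) / 99 + 0.3^2 * P2 * (1 - P2) / 99
  expect_equal(varianceOA(C, W), vOA, tolerance = 1e-12)
  expect_equal(varianceUA(C, W, 2L), 0.3^2 * P2 * (1 - P2) / 99,
               tolerance = 1e-12)
  expect_equal(varianceUA(C, W, 2L, mode = "standard"),
               P2 * (1 - P2) / 99, tolerance = 1e-12)
  # V(R_2) per the printed recall variance
  A1 <- 7000; A2 <- 3000
  Nhat <- A1 * 10 / 100 + A2 * 80 / 100
  R2 <- (W@w[2] * 80 / 100) / (W@w[1] * 10 / 100 + W@w[2] * 80 / 100)
  term1 <- A2^2 * (1 - R2)^2 * P2 * (1 - P2) / 99
  q12 <- 10 / 100
  term2 <- R2^2 * A1^2 * q12 * (1 - q12) / 99
  expect_equal(variancePA(C, W, A, 2L), (term1 + term2) / Nhat^2,
               tolerance = 1e-12)
  # degenerate strata: P in {0, 1} gives zero variance
  Cd <- confusionMatrix(100, 0, 0, 50)
  expect_equal(varianceOA(Cd, W), 0)
  # fewer than 2 samples in a weighted stratum: SE 0 with a warning
  C1 <- confusionMatrix(90, 10, 1, 0)
  expect_warning(v <- varianceUA(C1, W, 2L), "undefined")
  expect_equal(v, 0)
})

test_that("F1 and its propagated error follow the relative-error rule", {
  f <- f1WithError(metricEstimate(0.5, 0), metricEstimate(0.5, 0))
  expect_equal(metricValue(f), 0.5)
  expect_equal(metricSE(f), 0)
  f2 <- f1WithError(metricEstimate(0.8, 0.05), metricEstimate(0.6, 0.04))
  expect_equal(metricValue(f2), 0.96 / 1.4, tolerance = 1e-9)
  expect_equal(metricSE(f2), 0.132653, tolerance = 1e-6)
  # degenerate P = R = 0
  f0 <- f1WithError(metricEstimate(0, 0.1), metricEstimate(0, 0.2))
  expect_equal(metricValue(f0), 0)
  expect_equal(metricSE(f0), 0)
  expect_error(f1WithError(metricEstimate(0.5, -0.1), metricEstimate(0.5, 0)),
               "non-negative")
  # symmetric under swapping (P, dP) with (R, dR)
  set.seed(20)
  for (k in 1:20) {
    p <- runif(1); r <- runif(1); dp <- runif(1, 0, 0.1); dr <- runif(1, 0, 0.1)
    a <- f1WithError(metricEstimate(p, dp), metricEstimate(r, dr))
    b <- f1WithError(metricEstimate(r, dr), metricEstimate(p, dp))
    expect_equal(metricValue(a), metricValue(b), tolerance = 1e-12)
    expect_equal(metricSE(a), metricSE(b), tolerance = 1e-12)
  }
})

test_that("metric values stay in [0,1] with non-negative SEs on random data", {
  g <- localGrid(12L)
  set.seed(30)
  for (k in 1:20) {
    m <- randomBinaryMap(g, runif(1, 0.1, 0.9))
    ds <- countDataset(g, sample(10:30, 1), sample(10:30, 1))
    ev <- evaluateMap(m, ds)
    v <- metricValue(ev)
    s <- metricSE(ev)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(s >= 0))
  }
})

test_that("reduction: with W at sample proportions, metrics match plain counts", {
  # choose counts whose row proportions we can impose as W exactly
  C <- confusionMatrix(60, 20, 10, 110)
  W <- new("AreaWeights", w = c(80, 120) / 200)
  E <- populationMatrix(C, W)
  cts <- confusionCounts(C)
  expect_equal(overallAccuracy(E), sum(diag(cts)) / sum(cts))
  expect_equal(usersAccuracy(E, 2L), 110 / 120)
  expect_equal(producersAccuracy(E, 2L), 110 / 130)
})

test_that("evaluateMap runs the whole chain on the worked example", {
  g <- localGrid(10L)
  set.seed(40)
  mali <- countDataset(g, 10L, 437L, region = "Mali")
  m0 <- binaryCropMap(g, matrix(0, 10L, 10L),
                      mapMetadata("esri", 10, 2020L))
  ev <- evaluateMap(m0, mali)
  expect_equal(round(metricValue(ev)[["oa"]], 2), 0.98)
  expect_equal(unname(metricValue(ev)[c("ua", "pa", "f1")]), c(0, 0, 0))
  expect_equal(unname(metricSE(ev)[c("ua", "pa", "f1")]), c(0, 0, 0))
  # a map identical to truth with noise-free reference: all 1.00 +/- 0.00
  tr <- randomBinaryMap(g, 0.4)
  loc <- data.frame(x = runif(60, 0, 10 - 1e-9), y = runif(60, 1e-9, 10 - 1e-9))
  ds <- referenceDatasetFromLabels(loc, extractAt(tr, loc$x, loc$y))
  evp <- evaluateMap(tr, ds)
  expect_equal(unname(metricValue(evp)), rep(1, 4))
  expect_equal(unname(metricSE(evp)), rep(0, 4))
})
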