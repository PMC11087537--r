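test_that("binarization rules match their product conventions", {
  g <- localGrid(1L, 3L, ymax = 1)
  prob <- classRaster(g, matrix(c(0.6, 0.5, 0.2), 1L))
  expect_equal(as.vector(rasterValues(binarize(prob, thresholdRule(0.5)))),
               c(1, 0, 0))
  frac <- classRaster(g, matrix(c(50, 4, 96), 1L))
  expect_equal(as.vector(rasterValues(binarize(frac,
                                               fractionRangeRule(5, 95)))),
               c(1, 0, 0))
  # inclusive at both fraction ends
  ends <- classRaster(g, matrix(c(5, 95, 95.5), 1L))
  expect_equal(as.vector(rasterValues(binarize(ends,
                                               fractionRangeRule(5, 95)))),
               c(1, 1, 0))
  codes <- classRaster(g, matrix(c(11, 30, 14), 1L))
  expect_equal(as.vector(rasterValues(binarize(codes,
                                               codeSetRule(c(11, 14, 20))))),
               c(1, 0, 1))
  # domain mismatch: fraction rule on a raster outside [0, 100]
  bad <- classRaster(g, matrix(c(150, 20, 30), 1L))
  expect_error(binarize(bad, fractionRangeRule(5, 95)), "fraction")
  nonint <- classRaster(g, matrix(c(0.5, 1, 2), 1L))
  expect_error(binarize(nonint, codeSetRule(1)), "integer")
  # nodata preserved
  withNA <- classRaster(g, matrix(c(0.9, NA, 0.1), 1L))
  expect_equal(as.vector(rasterValues(binarize(withNA, thresholdRule(0.5)))),
               c(1, NA, 0))
})

test_that("mode composite takes the most frequent class, ties to lowest code", {
  g <- localGrid(2L, 2L)
  mk <- function(v) classRaster(g, matrix(v, 2L))
  stack <- list(mk(c(4, 4, 1, 9)), mk(c(4, 7, 2, 9)), mk(c(7, 7, 1, NA)))
  mc <- modeComposite(stack)
  expect_equal(as.vector(rasterValues(mc)), c(4, 7, 1, 9))
  expect_equal(rasterValues(modeComposite(list(mk(1:4), mk(1:4)))),
               matrix(1:4, 2L))
  expect_error(modeComposite(list()), "empty")
  # tie [4, 7] -> 4, against an exhaustive frequency-count oracle
  set.seed(31)
  for (k in 1:20) {
    series <- sample(c(1, 3, 7, NA), 5, replace = TRUE)
    stack <- lapply(series, function(s) mk(rep(s, 4)))
    got <- rasterValues(modeComposite(stack))[1L, 1L]
    expect_identical(got, oracleModeLowestTie(series))
  }
})

test_that("nearest-neighbor resampling nests exactly and matches the oracle", {
  # 20 m map onto aligned 10 m grid: each pixel becomes a 2x2 block
  g20 <- gridSpecNew(0, 80, 20, 4L, 4L)
  set.seed(5)
  m20 <- randomBinaryMap(g20)
  g10 <- gridSpecNew(0, 80, 10, 8L, 8L)
  m10 <- resampleToGrid(m20, g10)
  expect_equal(rasterValues(m10),
               rasterValues(m20)[rep(1:4, each = 2), rep(1:4, each = 2)])
  # identity on the same grid
  expect_identical(rasterValues(resampleToGrid(m20, g20)),
                   rasterValues(m20))
  # disjoint grids error
  far <- gridSpecNew(1000, 1080, 10, 4L, 4L)
  expect_error(resampleToGrid(m20, far), "overlap")
  # misaligned grids against the brute-force containing-cell oracle
  set.seed(8)
  for (k in 1:25) {
    src <- gridSpecNew(runif(1, -3, 3), runif(1, 5, 15),
                       sample(c(0.5, 1, 1.5, 2), 1),
                       sample(3:10, 1), sample(3:10, 1))
    m <- randomBinaryMap(src, pNodata = 0.1)
    tgt <- gridSpecNew(src@xmin + runif(1, -1, 1),
                       src@ymax + runif(1, -1, 1),
                       sample(c(0.7, 1, 1.3), 1),
                       sample(3:10, 1), sample(3:10, 1))
    ok <- tryCatch({resampleToGrid(m, tgt); TRUE},
                   error = function(e) FALSE)
    if (!ok) next
    expect_equal(rasterValues(resampleToGrid(m, tgt)), oracleResample(m, tgt))
  }
})

test_that("binarize and resample commute on exactly nested grids", {
  g20 <- gridSpecNew(0, 80, 20, 4L, 4L)
  g10 <- gridSpecNew(0, 80, 10, 8L, 8L)
  set.seed(12)
  prob <- classRaster(g20, matrix(runif(16), 4L))
  rule <- thresholdRule(0.5)
  a <- resampleToGrid(binarize(prob, rule), g10)
  # resample the probability raster by wrapping it in a map-like lookup
  probUp <- classRaster(g10, vapply(1:8, function(cc)
    vapply(1:8, function(r)
      rasterValues(prob)[ceiling(r / 2), ceiling(cc / 2)], numeric(1)),
    numeric(8)))
  b <- binarize(probUp, rule)
  expect_equal(rasterValues(a), rasterValues(b))
})

test_that("clipping keeps retained pixels bit-exact and matches oracles", {
  g <- localGrid(4L)
  set.seed(3)
  m <- randomBinaryMap(g)
  full <- clipToBoundary(m, squarePoly(-1, -1, 5, 5))
  expect_identical(rasterValues(full), rasterValues(m))
  # left half: right 8 pixels nodata
  half <- clipToBoundary(m, squarePoly(0, 0, 2, 4))
  expect_identical(rasterValues(half)[, 1:2], rasterValues(m)[, 1:2])
  expect_true(all(is.na(rasterValues(half)[, 3:4])))
  expect_warning(clipToBoundary(m, squarePoly(10, 10, 12, 12)), "disjoint")

  # random polygons against an independent point-in-polygon routine
  set.seed(99)
  for (k in 1:15) {
    gg <- localGrid(sample(4:10, 1), sample(4:10, 1))
    mm <- randomBinaryMap(gg)
    poly <- randomPolygon(cx = runif(1, 1, 5), cy = runif(1, 1, 5),
                          rmin = 1, rmax = 5)
    clipped <- suppressWarnings(clipToBoundary(mm, poly))
    keep <- oracleClipMask(gg, poly)
    expect_identical(is.na(rasterValues(clipped)),
                     !keep | is.na(rasterValues(mm)))
    expect_identical(rasterValues(clipped)[keep], rasterValues(mm)[keep])
  }
})

test_that("pointInPolygon agrees with mgcv off the edge and is edge-inclusive", {
  set.seed(17)
  for (k in 1:10) {
    poly <- randomPolygon(nVertices = sample(5:9, 1))
    px <- runif(200, -4, 4)
    py <- runif(200, -4, 4)
    expect_identical(pointInPolygon(px, py, poly),
                     as.vector(mgcv::in.out(poly, cbind(px, py))))
  }
  sq <- squarePoly(0, 0, 2, 2)
  expect_true(all(pointInPolygon(c(0, 2, 1, 0), c(0, 2, 0, 1), sq)))
  expect_false(pointInPolygon(2.0001, 1, sq))
})

test_that("mapped area counts non-nodata pixels per class", {
  g <- localGrid(10L)
  allCrop <- binaryCropMap(g, matrix(1, 10L, 10L))
  a <- mappedArea(allCrop)
  expect_equal(c(a@nNeg, a@nPos), c(0, 100))
  expect_equal(areaWeights(a)@w, c(0, 1))
  # all-non-crop map: W = [1, 0]
  w0 <- areaWeights(mappedArea(binaryCropMap(g, matrix(0, 10L, 10L))))
  expect_equal(w0@w, c(1, 0))
  expect_error(mappedArea(binaryCropMap(g, matrix(NA_real_, 10L, 10L))),
               "no non-nodata")
  # counts equal brute-force enumeration; classes partition non-nodata pixels
  set.seed(2)
  for (k in 1:10) {
    m <- randomBinaryMap(g, pCrop = runif(1), pNodata = 0.2)
    v <- rasterValues(m)
    n0 <- 0L; n1 <- 0L
    for (z in v) {
      if (is.na(z)) next
      if (z == 0) n0 <- n0 + 1L else n1 <- n1 + 1L
    }
    a <- mappedArea(m)
    expect_equal(c(a@nNeg, a@nPos), c(n0, n1))
    expect_equal(a@nNeg + a@nPos, sum(!is.na(v)))
  }
})
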