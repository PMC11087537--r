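test_that("true landscape hits the target crop fraction and is deterministic", {
  sc <- syntheticScenario(1L, localGrid(100L, pixel = 10, ymax = 1000),
                          cropFraction = 0.5)
  tr <- generateTrueLandscape(sc)
  nCrop <- sum(rasterValues(tr) == 1)
  expect_gte(nCrop, 4800)
  expect_lte(nCrop, 5200)
  expect_identical(rasterValues(generateTrueLandscape(sc)),
                   rasterValues(tr))

  sc2 <- syntheticScenario(7L, localGrid(200L, pixel = 10, ymax = 2000),
                           cropFraction = 0.3)
  v <- rasterValues(generateTrueLandscape(sc2))
  # exhaustive pixel count oracle
  count <- 0L
  for (k in seq_along(v)) if (v[k] == 1) count <- count + 1L
  expect_equal(count / length(v), 0.3, tolerance = 0.02)
})

test_that("landscape patches are spatially autocorrelated, not iid", {
  sc <- syntheticScenario(3L, localGrid(100L), cropFraction = 0.4)
  v <- rasterValues(generateTrueLandscape(sc))
  # neighbor concordance far above the iid expectation p^2 + (1-p)^2
  same <- mean(v[, -1] == v[, -ncol(v)])
  expect_gt(same, 0.8)
  expect_error(generateTrueLandscape(
    syntheticScenario(1L, gridSpecNew(0, 0, 1, 0, 0), cropFraction = 0.5)),
    "grid|row")
})

test_that("degradeMap honors its flip model in the extremes", {
  sc <- syntheticScenario(11L, localGrid(60L), cropFraction = 0.3)
  tr <- generateTrueLandscape(sc)
  clean <- degradeMap(tr, productSpec("p0", 1, 2019, 0, 0), 5L)
  expect_identical(rasterValues(clean), rasterValues(tr))
  allNeg <- degradeMap(tr, productSpec("p1", 1, 2019, 1, 0), 5L)
  expect_true(all(rasterValues(allNeg) == 0))
})

test_that("degradeMap aggregates coarse products by majority, ties non-crop", {
  g <- localGrid(4L)
  # 2x2 blocks: [1 1 / 1 0] -> crop; [1 0 / 0 1] tie -> non-crop;
  # [0 0 / 0 1] -> non-crop; [1 1 / 1 1] -> crop
  v <- rbind(c(1, 1, 1, 0), c(1, 0, 0, 1), c(0, 0, 1, 1), c(0, 1, 1, 1))
  tr <- binaryCropMap(g, v)
  coarse <- degradeMap(tr, productSpec("c", 2, 2019, 0, 0), 1L)
  expect_equal(gridSpec(coarse)@pixel, 2)
  expect_equal(rasterValues(coarse), rbind(c(1, 0), c(0, 1)))
})

test_that("degraded maps recover closed-form PA and UA over replicates", {
  o <- 0.2; cm <- 0.05; f <- 0.3
  sc <- syntheticScenario(21L, localGrid(100L), cropFraction = f)
  tr <- generateTrueLandscape(sc)
  tv <- rasterValues(tr)
  pa <- ua <- numeric(20)
  for (k in 1:20) {
    dm <- degradeMap(tr, productSpec("d", 1, 2019, o, cm), 100L + k)
    dv <- rasterValues(dm)
    pa[k] <- sum(dv == 1 & tv == 1) / sum(tv == 1)
    ua[k] <- sum(dv == 1 & tv == 1) / sum(dv == 1)
  }
  expPA <- 1 - o
  expUA <- (1 - o) * f / ((1 - o) * f + cm * (1 - f))
  expect_lt(abs(mean(pa) - expPA), 3 * sd(pa) / sqrt(20))
  expect_lt(abs(mean(ua) - expUA), 3 * sd(ua) / sqrt(20))
})

test_that("interpreter labels follow the noise model", {
  truth <- rbinom(10000, 1L, 0.3)
  labs0 <- generateInterpreterLabels(truth, 2L, 0, 77L)
  expect_true(all(labs0[, 1L] == truth & labs0[, 2L] == truth))
  expect_error(generateInterpreterLabels(truth, 2L, 0.5, 1L),
               "uninformative")
  expect_error(generateInterpreterLabels(truth, 1L, 0.1, 1L), "two")

  # unanimity fraction ~ (1-e)^2 + e^2 = 0.82 at e = 0.1
  labs <- generateInterpreterLabels(truth, 2L, 0.1, 42L)
  unan <- mean(labs[, 1L] == labs[, 2L])
  expect_lt(abs(unan - 0.82), 3 * sqrt(0.82 * 0.18 / 10000))

  # among unanimous triples, wrong-label fraction ~ e^3/((1-e)^3 + e^3)
  truth3 <- rbinom(100000, 1L, 0.5)
  labs3 <- generateInterpreterLabels(truth3, 3L, 0.1, 43L)
  unan3 <- labs3[, 1L] == labs3[, 2L] & labs3[, 2L] == labs3[, 3L]
  wrong <- mean(labs3[unan3, 1L] != truth3[unan3])
  pWrong <- 0.001 / (0.729 + 0.001)
  expect_lt(abs(wrong - pWrong),
            3 * sqrt(pWrong * (1 - pWrong) / sum(unan3)))
})

test_that("generators are pure functions of their seed", {
  sc <- syntheticScenario(9L, localGrid(30L), cropFraction = 0.4,
                          products = list(productSpec("p", 1, 2019, 0.2, 0.1)))
  tr <- generateTrueLandscape(sc)
  expect_identical(rasterValues(degradeMap(tr, sc@products[[1L]], 3L)),
                   rasterValues(degradeMap(tr, sc@products[[1L]], 3L)))
  expect_identical(generateInterpreterLabels(c(0, 1, 1), 3L, 0.2, 5L),
                   generateInterpreterLabels(c(0, 1, 1), 3L, 0.2, 5L))
  c1 <- generateNdviCube(sc, tr)
  c2 <- generateNdviCube(sc, tr)
  expect_identical(rasterValues(c1), rasterValues(c2))
  # generators leave the caller's RNG stream untouched
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(generateTrueLandscape(sc)); b <- runif(1)
  expect_identical(a, b)
})

test_that("NDVI cube follows its seasonal construction", {
  sc <- syntheticScenario(5L, localGrid(20L), cropFraction = 0.5,
                          ndviParams = within(defaultNdviParams(),
                                              noiseSd <- 0))
  tr <- generateTrueLandscape(sc)
  cube <- generateNdviCube(sc, tr)
  p <- sc@ndviParams
  arr <- rasterValues(cube)
  # noise-free pixels equal their deterministic sinusoid
  isCrop <- rasterValues(tr) == 1
  for (k in c(1L, 7L, 15L)) {
    season <- sin(2 * pi * (k - 1) / p$nTimesteps)
    expected <- ifelse(isCrop, p$cropBaseline + p$cropAmplitude * season,
                       p$noncropBaseline + p$noncropAmplitude * season)
    expect_equal(arr[, , k], expected, tolerance = 1e-12)
  }
  # crop exceeds non-crop at the seasonal peak
  peak <- which.max(sin(2 * pi * (seq_len(p$nTimesteps) - 1) /
                          p$nTimesteps))
  expect_gt(mean(arr[, , peak][isCrop]), mean(arr[, , peak][!isCrop]))

  # masked mean against brute-force per-pixel averaging
  scN <- syntheticScenario(5L, localGrid(20L), cropFraction = 0.5)
  cubeN <- generateNdviCube(scN, tr)
  ser <- maskedNdviSeries(cubeN, tr)
  band <- rasterValues(cubeN)[, , 3L]
  acc <- 0; nsel <- 0L
  for (r in 1:20) for (cc in 1:20) {
    if (rasterValues(tr)[r, cc] == 1) {
      acc <- acc + band[r, cc]
      nsel <- nsel + 1L
    }
  }
  expect_equal(ser$mean_ndvi[3L], acc / nsel, tolerance = 1e-12)
})
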