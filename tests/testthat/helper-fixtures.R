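# Small in-code fixtures shared across the suite.

localGrid <- function(nrow = 8L, ncol = nrow, pixel = 1, xmin = 0,
                      ymax = nrow * pixel) {
  gridSpecNew(xmin, ymax, pixel, nrow, ncol)
}

randomBinaryMap <- function(grid, pCrop = 0.5, pNodata = 0,
                            name = "random", res = grid@pixel,
                            year = 2019L) {
  v <- matrix(rbinom(grid@nrow * grid@ncol, 1L, pCrop), grid@nrow)
  if (pNodata > 0) {
    v[runif(length(v)) < pNodata] <- NA
  }
  binaryCropMap(grid, v, mapMetadata(name, res, year))
}

squarePoly <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
        c(xmin, ymin))
}

# convex random polygon: points on a jittered circle, angle-sorted
randomPolygon <- function(cx = 0, cy = 0, rmin = 1, rmax = 3,
                          nVertices = 7L) {
  ang <- sort(runif(nVertices, 0, 2 * pi))
  r <- runif(nVertices, rmin, rmax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# a reference dataset with known counts at generic in-grid locations
countDataset <- function(grid, nCrop, nNonCrop, region = "region",
                         year = 2019L) {
  n <- nCrop + nNonCrop
  ext <- gridExtent(grid)
  loc <- data.frame(
    x = runif(n, ext["xmin"], ext["xmax"] - 1e-9),
    y = runif(n, ext["ymin"] + 1e-9, ext["ymax"] - 1e-9))
  referenceDatasetFromLabels(loc, c(rep(1L, nCrop), rep(0L, nNonCrop)),
                             region = region, year = year)
}
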