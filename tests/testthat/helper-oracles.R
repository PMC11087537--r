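# Independent brute-force oracles. These deliberately use naive loops and
# direct definitions, sharing no code path with the package implementation.

# containing cell by direct interval comparison: [left, right) x (top, bottom]
# (top edge exclusive, bottom edge inclusive)
oracleCellLookup <- function(grid, x, y) {
  for (r in seq_len(grid@nrow)) {
    top <- grid@ymax - (r - 1) * grid@pixel
    bottom <- grid@ymax - r * grid@pixel
    if (y < top && y >= bottom) {
      for (cc in seq_len(grid@ncol)) {
        left <- grid@xmin + (cc - 1) * grid@pixel
        right <- grid@xmin + cc * grid@pixel
        if (x >= left && x < right) {
          return(c(row = r, col = cc))
        }
      }
    }
  }
  c(row = NA_integer_, col = NA_integer_)
}

oracleResample <- function(map, target) {
  out <- matrix(NA_real_, target@nrow, target@ncol)
  for (r in seq_len(target@nrow)) {
    for (cc in seq_len(target@ncol)) {
      x <- target@xmin + (cc - 0.5) * target@pixel
      y <- target@ymax - (r - 0.5) * target@pixel
      idx <- oracleCellLookup(map@grid, x, y)
      if (!is.na(idx["row"])) {
        out[r, cc] <- rasterValues(map)[idx["row"], idx["col"]]
      }
    }
  }
  out
}

oracleConfusion <- function(points, map) {
  cts <- matrix(0L, 2L, 2L)
  for (i in seq_len(nrow(points))) {
    idx <- oracleCellLookup(map@grid, points$x[i], points$y[i])
    if (is.na(idx["row"])) next
    v <- rasterValues(map)[idx["row"], idx["col"]]
    if (is.na(v)) next
    cts[v + 1L, points$final_label[i] + 1L] <-
      cts[v + 1L, points$final_label[i] + 1L] + 1L
  }
  cts
}

oraclePopulationMatrix <- function(counts, w) {
  p <- matrix(0, 2L, 2L)
  for (i in 1:2) {
    rowTot <- counts[i, 1L] + counts[i, 2L]
    for (j in 1:2) {
      if (w[i] > 0) {
        p[i, j] <- w[i] * counts[i, j] / rowTot
      }
    }
  }
  p
}

oraclePairAgreement <- function(a, b) {
  num <- 0L
  den <- 0L
  va <- rasterValues(a)
  vb <- rasterValues(b)
  for (k in seq_along(va)) {
    if (!is.na(va[k]) && !is.na(vb[k])) {
      den <- den + 1L
      if (va[k] == vb[k]) num <- num + 1L
    }
  }
  num / den
}

oracleConsensusSummary <- function(votes, K) {
  votes <- votes[!is.na(votes)]
  n <- length(votes)
  allCrop <- 0L; noneCrop <- 0L; split <- 0L
  lo <- floor(K / 2); hi <- ceiling(K / 2)
  for (v in votes) {
    if (v == K) allCrop <- allCrop + 1L
    if (v == 0) noneCrop <- noneCrop + 1L
    if ((v == lo || v == hi) && v != 0 && v != K) split <- split + 1L
  }
  c(all_same = 100 * (allCrop + noneCrop) / n,
    all_crop = 100 * allCrop / n,
    split = 100 * split / n,
    none_crop = 100 * noneCrop / n)
}

# clip oracle: per-center point-in-polygon via mgcv (independent routine)
oracleClipMask <- function(grid, boundary) {
  bnd <- as.matrix(boundary)
  keep <- matrix(FALSE, grid@nrow, grid@ncol)
  for (r in seq_len(grid@nrow)) {
    for (cc in seq_len(grid@ncol)) {
      x <- grid@xmin + (cc - 0.5) * grid@pixel
      y <- grid@ymax - (r - 0.5) * grid@pixel
      keep[r, cc] <- mgcv::in.out(bnd, c(x, y))
    }
  }
  keep
}

oracleModeLowestTie <- function(series) {
  series <- series[!is.na(series)]
  if (!length(series)) return(NA_real_)
  uu <- sort(unique(series))
  freq <- vapply(uu, function(u) sum(series == u), numeric(1))
  uu[which.max(freq)]  # which.max takes the first (lowest) on ties
}
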