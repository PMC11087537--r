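#' @include AllClasses.R AllGenerics.R raster.R
NULL

#' Per-pixel crop vote counts across maps
#'
#' Sums the crop votes of K binary maps on one grid. A pixel where any
#' constituent map is nodata is nodata in the result, so vote counts are
#' comparable across pixels.
#'
#' @param maps List of >= 2 [BinaryCropMap-class] on identical grids.
#' @return A [ConsensusRaster-class] with values in 0..K.
#' @export
consensusRaster <- function(maps) {
  if (length(maps) < 2L) stop("at least two maps are required")
  stopifnot(all(vapply(maps, is, logical(1), "BinaryCropMap")))
  g <- maps[[1L]]@grid
  for (m in maps) {
    if (!sameGrid(m@grid, g)) stop("all maps must share one grid")
  }
  votes <- matrix(0, g@nrow, g@ncol)
  anyNA <- matrix(FALSE, g@nrow, g@ncol)
  for (m in maps) {
    v <- m@values
    anyNA <- anyNA | is.na(v)
    v[is.na(v)] <- 0
    votes <- votes + v
  }
  votes[anyNA] <- NA
  new("ConsensusRaster", grid = g, values = votes,
      nMaps = length(maps))
}

#' Consensus summary statistics
#'
#' Percentages of non-nodata pixels where all K maps predict crop
#' (`pct_all_crop`, votes = K), where none do (`pct_none_crop`, votes = 0),
#' their sum (`pct_all_same`, unanimous either way), and where the vote is
#' as evenly split as possible (`pct_split`, votes in
#' `{floor(K/2), ceiling(K/2)}`, e.g. 5 or 6 of 11).
#'
#' @param cr A [ConsensusRaster-class] with at least one non-nodata pixel.
#' @return One-row data frame of the four percentages (of total non-nodata
#'   pixels).
#' @export
consensusSummary <- function(cr) {
  stopifnot(is(cr, "ConsensusRaster"))
  v <- cr@values[!is.na(cr@values)]
  if (!length(v)) stop("consensus raster has no non-nodata pixels")
  K <- cr@nMaps
  splitSet <- setdiff(unique(c(floor(K / 2), ceiling(K / 2))), c(0, K))
  pctAllCrop <- 100 * mean(v == K)
  pctNoneCrop <- 100 * mean(v == 0)
  data.frame(pct_all_same = pctAllCrop + pctNoneCrop,
             pct_all_crop = pctAllCrop,
             pct_split = 100 * mean(v %in% splitSet),
             pct_none_crop = pctNoneCrop)
}

#' Pairwise agreement matrix
#'
#' Entry (i, j) is the fraction of pixels where maps i and j predict the
#' same class, over pixels where both are non-nodata. The diagonal is set to
#' 0 by convention (a map's self-agreement carries no information). Maps are
#' ordered by native resolution, fine to coarse, ties by name.
#'
#' @param maps List of >= 2 [BinaryCropMap-class] on one grid.
#' @return Symmetric K x K matrix with map names as dimnames.
#' @export
pairwiseAgreement <- function(maps) {
  if (length(maps) < 2L) stop("at least two maps are required")
  g <- maps[[1L]]@grid
  for (m in maps) {
    if (!sameGrid(m@grid, g)) stop("all maps must share one grid")
  }
  maps <- orderMapsByResolution(maps)
  K <- length(maps)
  nm <- vapply(maps, mapName, character(1))
  M <- matrix(0, K, K, dimnames = list(nm, nm))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      vi <- maps[[i]]@values
      vj <- maps[[j]]@values
      both <- !is.na(vi) & !is.na(vj)
      if (!any(both)) stop("maps share no valid pixels")
      M[i, j] <- M[j, i] <- mean(vi[both] == vj[both])
    }
  }
  M
}

#' Order maps by native resolution (fine to coarse, ties by name)
#' @param maps List of [BinaryCropMap-class].
#' @export
orderMapsByResolution <- function(maps) {
  res <- vapply(maps, nativeResolution, numeric(1))
  nm <- vapply(maps, mapName, character(1))
  maps[order(res, nm)]
}

#' Mean agreement matrix and within-row rank matrix
#'
#' Averages agreement matrices element-wise (e.g. across countries), then
#' ranks each row's off-diagonal entries from lowest (1) to highest (K-1)
#' agreement; ties take the lower column index first. Diagonals stay 0 in
#' the mean and NA in the ranks.
#'
#' @param matrices List of equal-dimension agreement matrices.
#' @return List with elements `mean` and `rank`.
#' @export
meanAndRankMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  d <- dim(matrices[[1L]])
  for (m in matrices) {
    if (!all(dim(m) == d)) stop("matrices must share dimensions")
  }
  meanM <- Reduce(`+`, matrices) / length(matrices)
  K <- d[1L]
  rankM <- matrix(NA_real_, K, K, dimnames = dimnames(matrices[[1L]]))
  for (i in seq_len(K)) {
    off <- setdiff(seq_len(K), i)
    rankM[i, off] <- rank(meanM[i, off], ties.method = "first")
  }
  list(mean = meanM, rank = rankM)
}

#' Majority-vote ensemble map
#'
#' A pixel is crop when strictly more than half the maps vote crop (votes >
#' K/2; for K = 11 that is 6 or more). An even split therefore goes to
#' non-crop. An explicit `threshold` (minimum votes for crop) can override
#' the strict-majority rule.
#'
#' @param cr A [ConsensusRaster-class].
#' @param threshold Optional integer: crop iff votes >= threshold.
#' @return A [BinaryCropMap-class] named `"majority_vote"`.
#' @export
majorityVote <- function(cr, threshold = NULL) {
  stopifnot(is(cr, "ConsensusRaster"))
  v <- cr@values
  crop <- if (is.null(threshold)) v > cr@nMaps / 2 else v >= threshold
  binaryCropMap(cr@grid, crop * 1,
                mapMetadata("majority_vote", cr@grid@pixel, 0L))
}
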