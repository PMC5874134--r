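## ROI consistency (mean within-ROI voxel correlation), within/between
## correlation distributions, the permutation t test, and size binning.

#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' Thin wrapper around \code{stats::cor} that validates its inputs and
#' signals zero-variance series as an undefined correlation (NA with a
#' warning) rather than raising an opaque error, so callers can skip the
#' pair and adjust their counts.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1], or NA when either series is constant.
#' @examples
#' pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 2L) stop("series must have length >= 2")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance series: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

## Correlation matrix of the rows of m, with constant rows mapped to NA
## (stats::cor would warn per column; one warning summarizing counts is
## issued by callers).
.rowCorMatrix <- function(m) {
  const <- rowVariance(m) == 0
  cm <- suppressWarnings(cor(t(m)))
  if (any(const)) {
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
  }
  attr(cm, "nConstant") <- sum(const)
  cm
}

#' ROI consistency: mean within-ROI voxel correlation
#'
#' The consistency of an ROI is the mean Pearson correlation over all
#' distinct pairs of its member voxels' time series (the ordered-pair
#' double sum with 1/(N(N-1)) normalization reduces to the unordered-pair
#' mean). An ROI whose voxels all share one time series attains the
#' theoretical maximum phi = 1.
#'
#' Raw correlations are averaged without Fisher transformation. Pairs
#' involving a zero-variance voxel are skipped with the pair count
#' adjusted and a warning; an ROI with fewer than 2 usable voxels gets
#' phi = NA.
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param parc a \linkS4class{Parcellation}.
#' @param roiId optional single ROI id; default computes all ROIs.
#' @param subjectId optional label copied into the result.
#' @return A data frame with columns roi_id, size, phi, n_pairs (pairs
#'   actually averaged) and, when given, subject_id.
#' @examples
#' lab <- array(1L, c(3, 1, 1))
#' vts <- VoxelTimeSeries(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 3, 2, 1)),
#'                        cbind(0:2, 0, 0))
#' roiConsistency(vts, Parcellation(lab))$phi  # -1/3
#' @export
roiConsistency <- function(vts, parc, roiId = NULL, subjectId = NULL) {
  stopifnot(is(vts, "VoxelTimeSeries"), is(parc, "Parcellation"))
  ids <- if (is.null(roiId)) parc@roiIds else as.integer(roiId)
  cc <- voxelCoords(vts)
  labvec <- parc@labels[cc + 1L]
  m <- assay(vts)
  res <- lapply(ids, function(id) {
    rows <- which(labvec == id)
    n <- length(rows)
    if (n < 2L) {
      warning(sprintf("ROI %d has fewer than 2 voxels: phi undefined", id))
      return(data.frame(roi_id = id, size = n, phi = NA_real_,
                        n_pairs = 0L))
    }
    cm <- .rowCorMatrix(m[rows, , drop = FALSE])
    if (attr(cm, "nConstant") > 0)
      warning(sprintf(
        "ROI %d: %d zero-variance voxel(s); involved pairs skipped",
        id, attr(cm, "nConstant")))
    v <- cm[upper.tri(cm)]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning(sprintf("ROI %d has no usable voxel pairs: phi undefined", id))
      return(data.frame(roi_id = id, size = n, phi = NA_real_,
                        n_pairs = 0L))
    }
    data.frame(roi_id = id, size = n, phi = mean(v[ok]),
               n_pairs = sum(ok))
  })
  out <- do.call(rbind, res)
  if (!is.null(subjectId)) out$subject_id <- subjectId
  out
}

#' Pooled within- and between-ROI voxel correlation distributions
#'
#' Pools Pearson correlations over all distinct same-ROI voxel pairs
#' (within) and over voxel pairs from different ROIs (between, the
#' reference distribution), then compares the two means with a
#' permutation-based two-tailed t test. ROIs are implicitly weighted by
#' their pair counts, as pooling implies.
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param parc a \linkS4class{Parcellation} with >= 2 ROIs.
#' @param pairCap between-pair budget; above it, between pairs are
#'   subsampled uniformly (seed-reproducible). Default 1e7.
#' @param nPermutations permutations for the t test (see
#'   \code{\link{permutationTTest}}).
#' @param seed seed for subsampling and the permutation test.
#' @return A list: within_values, between_values, within_mean,
#'   between_mean, t_statistic, p_value, n_permutations.
#' @export
withinBetweenDistributions <- function(vts, parc, pairCap = 1e7,
                                       nPermutations = 10000,
                                       seed = NULL) {
  stopifnot(is(vts, "VoxelTimeSeries"), is(parc, "Parcellation"))
  if (length(parc@roiIds) < 2L)
    stop("at least 2 ROIs are required for the between-ROI reference")
  cc <- voxelCoords(vts)
  labvec <- parc@labels[cc + 1L]
  keep <- labvec > 0L
  m <- assay(vts)[keep, , drop = FALSE]
  lab <- labvec[keep]
  cm <- .rowCorMatrix(m)
  if (attr(cm, "nConstant") > 0)
    warning(sprintf("%d zero-variance voxel(s); involved pairs skipped",
                    attr(cm, "nConstant")))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  same <- lab[ut[, 1L]] == lab[ut[, 2L]]
  within <- cm[ut[same, , drop = FALSE]]
  between <- cm[ut[!same, , drop = FALSE]]
  within <- within[!is.na(within)]
  between <- between[!is.na(between)]
  if (!length(within)) stop("no usable within-ROI pairs")
  if (!length(between)) stop("no usable between-ROI pairs")
  if (length(between) > pairCap)
    between <- withSeed(seed, sample(between, pairCap))
  tt <- permutationTTest(within, between, nPermutations = nPermutations,
                         seed = seed)
  list(within_values = within, between_values = between,
       within_mean = mean(within), between_mean = mean(between),
       t_statistic = tt$t, p_value = tt$p,
       n_permutations = tt$n_permutations)
}

## Pooled-variance two-sample t statistic from group sums over a pooled
## vector; vectorized over columns of an index matrix.
.pooledT <- function(pooled, pooled2, idxA, nA, nB) {
  sA <- colSums(matrix(pooled[idxA], nA))
  sA2 <- colSums(matrix(pooled2[idxA], nA))
  tot <- sum(pooled); tot2 <- sum(pooled2)
  sB <- tot - sA; sB2 <- tot2 - sA2
  vA <- (sA2 - sA^2 / nA) / (nA - 1)
  vB <- (sB2 - sB^2 / nB) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  (sA / nA - sB / nB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

#' Permutation-based two-tailed two-sample t test
#'
#' The statistic is the pooled-variance Student t on the observed
#' labeling; the null distribution is obtained by permuting group labels
#' uniformly at random, with the add-one-smoothed p value
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_permutations). When the
#' total number of distinct labelings is at most 20000 they are enumerated
#' exhaustively instead.
#'
#' @param sampleA,sampleB nonempty numeric vectors.
#' @param nPermutations number of random permutations (default 10000).
#' @param seed optional seed for the random permutations.
#' @return A list: t (observed statistic), p, n_permutations (labelings
#'   actually used), exhaustive (logical).
#' @examples
#' permutationTTest(c(1, 2), c(8, 9))  # exhaustive: 6 labelings, p = 3/7
#' @export
permutationTTest <- function(sampleA, sampleB, nPermutations = 10000,
                             seed = NULL) {
  if (!length(sampleA) || !length(sampleB))
    stop("both samples must be nonempty")
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  nA <- length(sampleA); nB <- length(sampleB)
  if (nA + nB < 3L) stop("too few observations for a t statistic")
  pooled <- c(sampleA, sampleB)
  pooled2 <- pooled^2
  tObs <- .pooledT(pooled, pooled2, matrix(seq_len(nA)), nA, nB)
  if (!is.finite(tObs))
    stop("zero pooled variance: t statistic undefined")
  nTotal <- suppressWarnings(choose(nA + nB, nA))
  exhaustive <- is.finite(nTotal) && nTotal <= 20000
  if (exhaustive) {
    idx <- combn(nA + nB, nA)
    K <- ncol(idx)
  } else {
    K <- as.integer(nPermutations)
    idx <- withSeed(seed, {
      vapply(seq_len(K), function(i) sample.int(nA + nB, nA),
             integer(nA))
    })
    idx <- matrix(idx, nrow = nA)
  }
  tPerm <- .pooledT(pooled, pooled2, idx, nA, nB)
  hits <- sum(abs(tPerm) >= abs(tObs) - 1e-12, na.rm = TRUE)
  list(t = tObs, p = (1 + hits) / (1 + K),
       n_permutations = K, exhaustive = exhaustive)
}

#' Bin ROI consistency by ROI size
#'
#' Pools consistency records (across subjects when present), assigns them
#' to logarithmically spaced size bins, and reports per-bin mean and
#' standard deviation of phi with occupancy, plus the overall Pearson
#' correlation between size and phi.
#'
#' @param records data frame from \code{\link{roiConsistency}} (columns
#'   size, phi; rows with NA phi are dropped).
#' @param nBins number of logarithmic size bins.
#' @return A list: binned (data frame bin, size_low, size_high, n,
#'   mean_phi, sd_phi), correlation, p_value.
#' @export
consistencyVsSize <- function(records, nBins = 10) {
  if (nBins < 1) stop("nBins must be >= 1")
  rec <- records[!is.na(records$phi), , drop = FALSE]
  if (!nrow(rec)) stop("no records with defined phi")
  lo <- min(rec$size); hi <- max(rec$size)
  breaks <- if (lo == hi) c(lo - 0.5, hi + 0.5)
            else exp(seq(log(lo), log(hi), length.out = nBins + 1))
  bin <- cut(rec$size, breaks, include.lowest = TRUE, labels = FALSE)
  binned <- do.call(rbind, lapply(sort(unique(bin)), function(bi) {
    ph <- rec$phi[bin == bi]
    data.frame(bin = bi, size_low = breaks[bi], size_high = breaks[bi + 1],
               n = length(ph), mean_phi = mean(ph),
               sd_phi = if (length(ph) > 1) sd(ph) else NA_real_)
  }))
  if (sd(rec$size) > 0 && sd(rec$phi) > 0 && nrow(rec) > 2) {
    ct <- cor.test(rec$size, rec$phi)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  list(binned = binned, correlation = r, p_value = p)
}
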