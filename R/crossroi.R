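## Inter-ROI correlations at the voxel level and the ROI level, their
## relation to consistency, and the identity-line bound check.

#' Voxel-level correlation between two ROIs
#'
#' The mean Pearson correlation over all N_I x N_J cross-ROI voxel pairs.
#' It equals 1 exactly when every voxel series in both ROIs is identical.
#' Pairs involving zero-variance voxels are skipped with the count
#' adjusted and a warning.
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param parc a \linkS4class{Parcellation}.
#' @param i,j distinct ROI ids.
#' @return The mean cross-pair correlation (NA if no usable pairs).
#' @export
voxelLevelCorrelation <- function(vts, parc, i, j) {
  stopifnot(is(vts, "VoxelTimeSeries"), is(parc, "Parcellation"))
  if (i == j) stop("ROIs must be distinct")
  cc <- voxelCoords(vts)
  labvec <- parc@labels[cc + 1L]
  m <- assay(vts)
  ri <- which(labvec == i); rj <- which(labvec == j)
  if (!length(ri) || !length(rj))
    stop("both ROIs must contain at least one voxel")
  mi <- m[ri, , drop = FALSE]; mj <- m[rj, , drop = FALSE]
  ci <- rowVariance(mi) == 0; cj <- rowVariance(mj) == 0
  if (any(ci) || any(cj))
    warning(sprintf(
      "%d zero-variance voxel(s) between ROIs %d and %d; pairs skipped",
      sum(ci) + sum(cj), i, j))
  if (all(ci) || all(cj)) return(NA_real_)
  block <- suppressWarnings(cor(t(mi[!ci, , drop = FALSE]),
                                t(mj[!cj, , drop = FALSE])))
  mean(block)
}

#' ROI-level correlation between two averaged series
#'
#' The Pearson correlation between the ROI time series X_I and X_J.
#' A constant averaged series (which can arise from exactly cancelling
#' voxels) makes the correlation undefined: NA with a warning.
#'
#' @param rts a \linkS4class{RoiTimeSeries}.
#' @param i,j distinct ROI ids.
#' @return The correlation, or NA when undefined.
#' @export
roiLevelCorrelation <- function(rts, i, j) {
  stopifnot(is(rts, "RoiTimeSeries"))
  if (i == j) stop("ROIs must be distinct")
  ids <- roiIds(rts)
  ki <- match(i, ids); kj <- match(j, ids)
  if (is.na(ki) || is.na(kj)) stop("ROI id not present")
  pearsonCor(assay(rts)[ki, ], assay(rts)[kj, ])
}

#' Per-pair table of consistency and inter-ROI correlations
#'
#' One row per unordered ROI pair with the pair's mean consistency
#' (phi_I + phi_J)/2, the voxel-level correlation c_vox, and the ROI-level
#' correlation c_roi. Rows with an undefined component are flagged, not
#' dropped. The attribute \code{"correlations"} holds the Pearson
#' correlations (with p values) of c_vox and of c_roi against mean
#' consistency across pairs, computed on complete rows.
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param rts the matching \linkS4class{RoiTimeSeries}.
#' @param parc the \linkS4class{Parcellation}.
#' @param consistencies optional result of \code{\link{roiConsistency}};
#'   computed when missing.
#' @return A data frame (roi_i, roi_j, mean_consistency, c_vox, c_roi,
#'   flag) with attribute \code{"correlations"}.
#' @export
buildPairTable <- function(vts, rts, parc, consistencies = NULL) {
  if (is.null(consistencies)) consistencies <- roiConsistency(vts, parc)
  ids <- parc@roiIds
  if (length(ids) < 2L) stop("at least 2 ROIs are required")
  phi <- consistencies$phi[match(ids, consistencies$roi_id)]
  pairs <- combn(seq_along(ids), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    cvox <- voxelLevelCorrelation(vts, parc, ids[a], ids[b])
    croi <- roiLevelCorrelation(rts, ids[a], ids[b])
    mc <- (phi[a] + phi[b]) / 2
    data.frame(roi_i = ids[a], roi_j = ids[b], mean_consistency = mc,
               c_vox = cvox, c_roi = croi,
               flag = is.na(mc) || is.na(cvox) || is.na(croi))
  })
  tbl <- do.call(rbind, rows)
  corRow <- function(y) {
    ok <- !tbl$flag
    if (sum(ok) > 2 && sd(tbl$mean_consistency[ok]) > 0 && sd(y[ok]) > 0) {
      ct <- cor.test(y[ok], tbl$mean_consistency[ok])
      c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    } else c(r = NA_real_, p = NA_real_, n = sum(ok))
  }
  attr(tbl, "correlations") <- data.frame(
    metric = c("c_vox", "c_roi"),
    rbind(corRow(tbl$c_vox), corRow(tbl$c_roi)))
  tbl
}

#' Check the identity-line bound c_vox <= mean consistency
#'
#' The population bound sqrt(a_I a_J) R_IJ + b <= (a_I + a_J)/2 + b means
#' voxel-level correlations never exceed the pair's mean consistency; in
#' samples the bound holds up to sampling noise. Returns the pairs that
#' violate it beyond the given tolerance (an empty result asserts the
#' bound).
#'
#' @param table a pair table from \code{\link{buildPairTable}}.
#' @param tolerance slack added to mean consistency.
#' @return The subset of rows with c_vox > mean_consistency + tolerance.
#' @export
identityBoundCheck <- function(table, tolerance = 0) {
  if (!nrow(table)) stop("pair table is empty")
  ok <- !is.na(table$c_vox) & !is.na(table$mean_consistency)
  table[ok & table$c_vox > table$mean_consistency + tolerance, ,
        drop = FALSE]
}

#' Equal-width binning of one pair-table field against another
#'
#' @param table a data frame (typically from \code{\link{buildPairTable}}).
#' @param xField,yField column names to bin over and to average.
#' @param nBins number of equal-width bins over the x range.
#' @return A data frame: bin, x_low, x_high, n, mean_y, sd_y.
#' @export
relationBinned <- function(table, xField, yField, nBins = 10) {
  if (nBins < 1) stop("nBins must be >= 1")
  if (!all(c(xField, yField) %in% names(table)))
    stop("fields not present in the table")
  x <- table[[xField]]; y <- table[[yField]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no complete rows to bin")
  lo <- min(x); hi <- max(x)
  breaks <- if (lo == hi) c(lo - 0.5, hi + 0.5)
            else seq(lo, hi, length.out = nBins + 1)
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  do.call(rbind, lapply(sort(unique(bin)), function(bi) {
    yy <- y[bin == bi]
    data.frame(bin = bi, x_low = breaks[bi], x_high = breaks[bi + 1],
               n = length(yy), mean_y = mean(yy),
               sd_y = if (length(yy) > 1) sd(yy) else NA_real_)
  }))
}
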