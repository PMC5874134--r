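## Signal transformations: linear detrending, mask-renormalized Gaussian
## spatial smoothing, and ROI averaging.

.detrendMatrix <- function(m) {
  nT <- ncol(m)
  if (nT < 3L) stop("detrending requires at least 3 time points")
  tt <- seq_len(nT) - 1
  X <- cbind(1, tt)
  ## least-squares fit per row: residual = m - m X (X'X)^-1 X'
  H <- X %*% solve(crossprod(X), t(X))
  m - m %*% t(H)
}

#' @rdname detrendLinear
setMethod("detrendLinear", "matrix", function(x) .detrendMatrix(x))

#' @rdname detrendLinear
setMethod("detrendLinear", "VoxelTimeSeries", function(x) {
  out <- x
  SummarizedExperiment::assay(out) <- .detrendMatrix(assay(x))
  out
})

#' @rdname detrendLinear
setMethod("detrendLinear", "RoiTimeSeries", function(x) {
  out <- x
  SummarizedExperiment::assay(out) <- .detrendMatrix(assay(x))
  out
})

#' Mask-renormalized isotropic Gaussian spatial smoothing
#'
#' Each time frame is convolved with an isotropic Gaussian of the kernel's
#' FWHM (in mm, converted to voxels per axis via the voxel size). Kernel
#' weights falling outside the mask are dropped and the remaining weights
#' rescaled to sum to one, so a spatially constant field is preserved
#' exactly and no power is lost at mask boundaries. The kernel is
#' truncated at the kernel's \code{truncationSigmas} (default 4) standard
#' deviations.
#'
#' @param vts a \linkS4class{VoxelTimeSeries} on a regular grid.
#' @param kernel a \linkS4class{SmoothingKernel}, or a FWHM in mm.
#' @param gridShape grid dimensions; defaults to the smallest grid
#'   containing all voxel coordinates.
#' @return A smoothed \linkS4class{VoxelTimeSeries} on the same voxels.
#' @examples
#' spec <- syntheticSpec(27, 40, sharedFraction = 0)
#' sm <- smoothSpatial(generateVoxelTimeSeries(spec), smoothingKernel(8))
#' @export
smoothSpatial <- function(vts, kernel, gridShape = NULL) {
  stopifnot(is(vts, "VoxelTimeSeries"))
  if (!is(kernel, "SmoothingKernel")) kernel <- smoothingKernel(kernel)
  if (kernel@fwhmMm == 0) return(vts)
  vox <- voxelSizeMm(vts)
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("voxel size must be known and positive for smoothing")
  cc <- voxelCoords(vts)
  if (is.null(gridShape)) gridShape <- apply(cc, 2L, max) + 1L
  taps <- lapply(1:3, function(ax)
    gaussianTaps(kernel@sigmaMm / vox[ax], kernel@truncationSigmas))

  conv3 <- function(arr) {
    for (ax in 1:3)
      if (!is.null(taps[[ax]])) arr <- convolveAxis(arr, taps[[ax]], ax)
    arr
  }
  mask <- array(0, gridShape)
  mask[cc + 1L] <- 1
  denom <- conv3(mask)
  m <- assay(vts)
  out <- matrix(0, nrow(m), ncol(m))
  frame <- array(0, gridShape)
  for (t in seq_len(ncol(m))) {
    frame[cc + 1L] <- m[, t]
    num <- conv3(frame)
    out[, t] <- num[cc + 1L] / denom[cc + 1L]
  }
  res <- vts
  SummarizedExperiment::assay(res) <- out
  res
}

#' Average voxel time series within ROIs
#'
#' The ROI signal is the unweighted time-point-wise mean of its member
#' voxels' series. Membership is looked up from the parcellation labels
#' at the voxel coordinates, so voxels removed upstream (masking, power
#' filter) simply do not contribute; an ROI left with no voxels is an
#' error.
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param parc a \linkS4class{Parcellation} on the same grid.
#' @return A \linkS4class{RoiTimeSeries}, rows ordered by ROI id, with the
#'   surviving voxel count per ROI in \code{roiSizes()}.
#' @examples
#' lab <- array(1L, c(2, 1, 1))
#' vts <- VoxelTimeSeries(rbind(c(0, 2), c(2, 0)), cbind(0:1, 0, 0))
#' assay(roiAverage(vts, Parcellation(lab)))  # [1, 1]
#' @export
roiAverage <- function(vts, parc) {
  stopifnot(is(vts, "VoxelTimeSeries"), is(parc, "Parcellation"))
  cc <- voxelCoords(vts)
  d <- dim(parc@labels)
  if (any(cc[, 1L] >= d[1] | cc[, 2L] >= d[2] | cc[, 3L] >= d[3]))
    stop("voxel coordinates fall outside the parcellation grid")
  labvec <- parc@labels[cc + 1L]
  missing <- setdiff(parc@roiIds, labvec)
  if (length(missing))
    stop(sprintf("ROI(s) %s have no surviving voxels",
                 paste(missing, collapse = ", ")))
  inroi <- labvec > 0L
  sums <- rowsum(assay(vts)[inroi, , drop = FALSE], labvec[inroi])
  ids <- as.integer(rownames(sums))
  ord <- order(ids)
  sums <- sums[ord, , drop = FALSE]
  ids <- ids[ord]
  counts <- as.integer(table(factor(labvec[inroi], levels = ids)))
  data <- sums / counts
  dimnames(data) <- NULL
  se <- SummarizedExperiment(
    assays = list(signal = data),
    rowData = DataFrame(roi_id = ids, size = counts))
  metadata(se)$voxelSizeMm <- voxelSizeMm(vts)
  new("RoiTimeSeries", se)
}
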