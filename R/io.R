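## NIfTI input and the low-power voxel exclusion filter.

#' Read a 4-D NIfTI image as a VoxelTimeSeries
#'
#' Voxels are masked either by an explicit 3-D mask image or, by default,
#' by the rule "nonzero anywhere in time". Rows are ordered
#' lexicographically by 0-based (x, y, z) grid index.
#'
#' @param path path to a 4-D NIfTI-1/2 image.
#' @param maskPath optional path to a 3-D mask image on the same grid;
#'   voxels with nonzero mask value are kept.
#' @return A \linkS4class{VoxelTimeSeries}; voxel size (and TR when the
#'   header carries one) are taken from the NIfTI header.
#' @export
readVoxelTimeSeries <- function(path, maskPath = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D image, got %d dimension(s)", length(d)))
  bad <- sum(!is.finite(img))
  if (bad > 0)
    stop(sprintf("image contains %d non-finite values", bad))
  pd <- RNifti::pixdim(img)
  vox <- pd[1:3]
  tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else NULL
  flat <- matrix(img, prod(d[1:3]), d[4])
  if (is.null(maskPath)) {
    keep <- rowSums(flat != 0) > 0
  } else {
    msk <- RNifti::readNifti(maskPath)
    if (!identical(as.integer(dim(msk)[1:3]), as.integer(d[1:3])))
      stop("mask grid does not match the image grid")
    keep <- as.vector(msk != 0)
  }
  if (!any(keep)) stop("mask removes every voxel")
  coords <- arrayInd(which(keep), d[1:3]) - 1L
  VoxelTimeSeries(flat[keep, , drop = FALSE], coords,
                  voxelSizeMm = vox, trSeconds = tr)
}

#' Read a 3-D label volume as a Parcellation
#'
#' The label grid must match the image's spatial grid. Voxels that are not
#' present in the \linkS4class{VoxelTimeSeries} (masked out or filtered)
#' are zeroed in the stored labels, so ROI sizes count only surviving
#' voxels.
#'
#' @param path path to a 3-D integer NIfTI label image (0 = background).
#' @param image the \linkS4class{VoxelTimeSeries} the labels apply to; when
#'   \code{NULL} all labeled voxels are kept.
#' @param gridShape spatial grid of the source image; required to check
#'   shape when \code{image} does not span the full grid. Defaults to the
#'   label grid itself.
#' @param roiNames optional ROI names in increasing label order.
#' @return A \linkS4class{Parcellation}.
#' @export
readParcellation <- function(path, image = NULL, gridShape = NULL,
                             roiNames = character()) {
  lab <- RNifti::readNifti(path)
  d <- dim(lab)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # dropped
                                                          # singleton dims
  if (length(d) != 3L) stop("label volume must be 3-D")
  if (!is.null(gridShape) &&
      !identical(as.integer(d), as.integer(gridShape)))
    stop(sprintf("label grid %s does not match image grid %s",
                 paste(d, collapse = "x"),
                 paste(gridShape, collapse = "x")))
  arr <- array(as.vector(lab), d)
  if (any(!is.finite(arr)) || any(arr != round(arr)))
    stop("labels must be finite integers")
  if (any(arr < 0)) stop("negative labels are not allowed")
  arr <- array(as.integer(round(arr)), d)
  if (!is.null(image)) {
    cc <- voxelCoords(image)
    if (any(cc[, 1L] >= d[1] | cc[, 2L] >= d[2] | cc[, 3L] >= d[3]))
      stop("image voxels fall outside the label grid")
    keep <- array(FALSE, d)
    keep[cc + 1L] <- TRUE
    arr[!keep] <- 0L
  }
  Parcellation(arr, roiNames = roiNames)
}

#' Exclude voxels whose signal power falls below a fraction of the mean
#'
#' Voxel signal power is the variance of its time series. Voxels with
#' power below \code{fraction} times the mean power over all voxels are
#' removed; this reproduces the edge-of-brain exclusion rule used when
#' cleaning resting-state data (default fraction 2\%).
#'
#' @param vts a \linkS4class{VoxelTimeSeries}.
#' @param fraction fraction of the mean power defining the cut, in (0, 1).
#' @param threshold optional absolute power threshold; overrides
#'   \code{fraction} (used to re-apply a recorded cut, which is idempotent).
#' @return A list with \code{vts} (the retained voxels) and \code{report},
#'   a data frame of removed voxels (columns x, y, z, power, threshold).
#' @examples
#' vts <- VoxelTimeSeries(rbind(10 * rnorm(50), 0.05 * rnorm(50)),
#'                        cbind(0:1, 0, 0))
#' filterLowPowerVoxels(vts)$report
#' @export
filterLowPowerVoxels <- function(vts, fraction = 0.02, threshold = NULL) {
  stopifnot(is(vts, "VoxelTimeSeries"))
  if (is.null(threshold)) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
    power <- rowVariance(assay(vts))
    threshold <- fraction * mean(power)
  } else {
    power <- rowVariance(assay(vts))
  }
  keep <- power >= threshold
  if (!any(keep))
    stop("low-power filter would remove every voxel (degenerate input)")
  cc <- voxelCoords(vts)
  report <- data.frame(x = cc[!keep, 1L], y = cc[!keep, 2L],
                       z = cc[!keep, 3L], power = unname(power[!keep]),
                       threshold = rep(threshold, sum(!keep)))
  rownames(report) <- NULL
  out <- vts[keep, ]
  out <- new("VoxelTimeSeries", out)
  attr(report, "threshold") <- threshold
  list(vts = out, report = report)
}

#' Write ROI time series as TSV
#'
#' Rows are ROIs, columns are time points, with roi_id (and name, when
#' available) leading.
#'
#' @param rts a \linkS4class{RoiTimeSeries}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeRoiTimeSeries <- function(rts, path) {
  df <- data.frame(roi_id = roiIds(rts), size = roiSizes(rts),
                   assay(rts), check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("t", seq_len(ncol(rts)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
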