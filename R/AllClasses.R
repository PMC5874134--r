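#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom SummarizedExperiment assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## VoxelTimeSeries
## ---------------------------------------------------------------------------

#' Voxel-level BOLD time series on a regular grid
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"signal"}
#' holds one row per voxel and one column per time point. Row metadata
#' carries the 0-based integer grid coordinates (\code{x}, \code{y},
#' \code{z}); object metadata carries the voxel edge lengths in mm and,
#' optionally, the repetition time in seconds.
#'
#' Voxel order is always lexicographic by (x, y, z); all constructors and
#' readers enforce it so that identical grids yield identical row order.
#'
#' @export
setClass("VoxelTimeSeries", contains = "SummarizedExperiment")

setValidity("VoxelTimeSeries", function(object) {
  m <- assay(object)
  rd <- rowData(object)
  if (!all(c("x", "y", "z") %in% colnames(rd)))
    return("rowData must contain integer coordinate columns x, y, z")
  if (ncol(m) < 2L)
    return("at least 2 time points are required")
  if (!all(is.finite(m)))
    return(sprintf("%d non-finite values in the signal matrix",
                   sum(!is.finite(m))))
  cc <- paste(rd$x, rd$y, rd$z)
  if (anyDuplicated(cc))
    return("voxel coordinates must be unique")
  vs <- metadata(object)$voxelSizeMm
  if (is.null(vs) || length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    return("metadata$voxelSizeMm must be 3 positive numbers")
  TRUE
})

#' Construct a VoxelTimeSeries
#'
#' @param data numeric matrix, voxels in rows, time points in columns.
#' @param coords integer matrix/data.frame with one row per voxel and
#'   columns x, y, z (0-based grid indices).
#' @param voxelSizeMm numeric length-3, voxel edge lengths in mm.
#' @param trSeconds optional repetition time in seconds.
#' @return A \linkS4class{VoxelTimeSeries} with rows sorted
#'   lexicographically by (x, y, z).
#' @examples
#' vts <- VoxelTimeSeries(matrix(rnorm(20), 2), coords = cbind(0:1, 0, 0))
#' voxelCoords(vts)
#' @export
VoxelTimeSeries <- function(data, coords, voxelSizeMm = c(4, 4, 4),
                            trSeconds = NULL) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) != nrow(data) || ncol(coords) != 3L)
    stop("'coords' must have one (x, y, z) row per voxel")
  colnames(coords) <- c("x", "y", "z")
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  data <- data[ord, , drop = FALSE]
  coords <- coords[ord, , drop = FALSE]
  dimnames(data) <- NULL
  se <- SummarizedExperiment(
    assays = list(signal = data),
    rowData = DataFrame(x = coords[, 1L], y = coords[, 2L], z = coords[, 3L]))
  metadata(se)$voxelSizeMm <- as.numeric(voxelSizeMm)
  metadata(se)$trSeconds <- trSeconds
  new("VoxelTimeSeries", se)
}

#' @rdname voxelCoords
setMethod("voxelCoords", "VoxelTimeSeries", function(x) {
  rd <- rowData(x)
  cbind(x = rd$x, y = rd$y, z = rd$z)
})

#' @rdname voxelSizeMm
setMethod("voxelSizeMm", "VoxelTimeSeries",
          function(x) metadata(x)$voxelSizeMm)

#' @rdname nTimepoints
setMethod("nTimepoints", "VoxelTimeSeries", function(x) ncol(x))

setMethod("show", "VoxelTimeSeries", function(object) {
  cat(sprintf("VoxelTimeSeries: %d voxels x %d time points\n",
              nrow(object), ncol(object)))
  cat(sprintf("  voxel size: %s mm\n",
              paste(voxelSizeMm(object), collapse = " x ")))
  tr <- metadata(object)$trSeconds
  if (!is.null(tr)) cat(sprintf("  TR: %g s\n", tr))
})

## ---------------------------------------------------------------------------
## Parcellation
## ---------------------------------------------------------------------------

#' ROI label volume
#'
#' A 3-D integer grid assigning every voxel to at most one Region of
#' Interest; label 0 marks background. ROI sizes are the label counts over
#' the stored grid, so a parcellation restricted to an analysis mask (see
#' \code{\link{readParcellation}}) already has out-of-mask voxels zeroed.
#'
#' @slot labels 3-D integer array of ROI labels (0 = background).
#' @slot roiIds sorted positive integer labels present in the grid.
#' @slot roiNames optional character names, parallel to \code{roiIds}.
#' @slot sizes integer voxel counts per ROI, parallel to \code{roiIds}.
#' @export
setClass("Parcellation",
  representation(labels = "array", roiIds = "integer",
                 roiNames = "character", sizes = "integer"))

setValidity("Parcellation", function(object) {
  lab <- object@labels
  if (length(dim(lab)) != 3L) return("'labels' must be a 3-D array")
  if (any(lab < 0L)) return("negative labels are not allowed")
  tab <- table(lab[lab > 0L])
  ids <- as.integer(names(tab))
  if (!identical(object@roiIds, ids))
    return("roiIds must equal the sorted positive labels present")
  if (!identical(object@sizes, as.integer(tab)))
    return("sizes must equal the label counts")
  if (length(object@roiNames) &&
      length(object@roiNames) != length(object@roiIds))
    return("roiNames must be empty or parallel to roiIds")
  TRUE
})

#' Construct a Parcellation from a label array
#'
#' @param labels 3-D integer array (0 = background).
#' @param roiNames optional character vector naming the ROIs in increasing
#'   label order.
#' @return A \linkS4class{Parcellation}.
#' @examples
#' lab <- array(0L, c(2, 2, 1)); lab[1:3] <- c(1L, 1L, 2L)
#' Parcellation(lab)
#' @export
Parcellation <- function(labels, roiNames = character()) {
  labels <- as.array(labels)
  if (any(labels != round(labels)))
    stop("labels must be integers")
  storage.mode(labels) <- "integer"
  tab <- table(labels[labels > 0L])
  new("Parcellation", labels = labels,
      roiIds = as.integer(names(tab)),
      roiNames = as.character(roiNames),
      sizes = as.integer(tab))
}

#' @rdname roiIds
setMethod("roiIds", "Parcellation", function(x) x@roiIds)

#' @rdname roiSizes
setMethod("roiSizes", "Parcellation", function(x) {
  s <- x@sizes
  names(s) <- x@roiIds
  s
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d ROIs on a %s grid (%d labeled voxels)\n",
              length(object@roiIds),
              paste(dim(object@labels), collapse = " x "),
              sum(object@sizes)))
  if (length(object@roiIds))
    cat(sprintf("  sizes: %s\n",
                paste(head(object@sizes, 8), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## RoiTimeSeries
## ---------------------------------------------------------------------------

#' ROI-averaged time series
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"signal"} holds
#' one row per ROI: the unweighted time-point-wise mean of the member voxel
#' series. Row metadata carries \code{roi_id} and \code{size} (number of
#' voxels averaged).
#'
#' @export
setClass("RoiTimeSeries", contains = "SummarizedExperiment")

setValidity("RoiTimeSeries", function(object) {
  rd <- rowData(object)
  if (!all(c("roi_id", "size") %in% colnames(rd)))
    return("rowData must contain roi_id and size")
  if (is.unsorted(rd$roi_id, strictly = TRUE))
    return("rows must be ordered by increasing roi_id")
  TRUE
})

#' @rdname roiIds
setMethod("roiIds", "RoiTimeSeries", function(x) rowData(x)$roi_id)

#' @rdname roiSizes
setMethod("roiSizes", "RoiTimeSeries", function(x) {
  s <- rowData(x)$size
  names(s) <- rowData(x)$roi_id
  s
})

#' @rdname nTimepoints
setMethod("nTimepoints", "RoiTimeSeries", function(x) ncol(x))

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d ROIs x %d time points\n",
              nrow(object), ncol(object)))
})

## ---------------------------------------------------------------------------
## SmoothingKernel
## ---------------------------------------------------------------------------

#' Isotropic Gaussian smoothing kernel
#'
#' Parameterized by its full width at half maximum in mm; the standard
#' deviation is derived as \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}. The
#' kernel is truncated at \code{truncationSigmas} standard deviations.
#'
#' @slot fwhmMm full width at half maximum, mm (0 = no smoothing).
#' @slot sigmaMm derived standard deviation, mm.
#' @slot truncationSigmas truncation radius in units of sigma.
#' @export
setClass("SmoothingKernel",
  representation(fwhmMm = "numeric", sigmaMm = "numeric",
                 truncationSigmas = "numeric"))

setValidity("SmoothingKernel", function(object) {
  if (object@fwhmMm < 0) return("fwhmMm must be nonnegative")
  expected <- object@fwhmMm / (2 * sqrt(2 * log(2)))
  if (object@fwhmMm > 0 &&
      abs(object@sigmaMm - expected) > 1e-12 * expected)
    return("sigmaMm inconsistent with fwhmMm")
  if (object@truncationSigmas <= 0) return("truncation must be positive")
  TRUE
})

#' @param fwhmMm full width at half maximum in mm.
#' @param truncationSigmas truncation radius in sigmas (default 4).
#' @return A \linkS4class{SmoothingKernel}.
#' @examples
#' smoothingKernel(8)  # sigma = 3.3973 mm
#' @rdname SmoothingKernel-class
#' @export
smoothingKernel <- function(fwhmMm, truncationSigmas = 4) {
  if (fwhmMm < 0) stop("fwhmMm must be nonnegative")
  new("SmoothingKernel", fwhmMm = as.numeric(fwhmMm),
      sigmaMm = fwhmMm / (2 * sqrt(2 * log(2))),
      truncationSigmas = as.numeric(truncationSigmas))
}

setMethod("show", "SmoothingKernel", function(object) {
  cat(sprintf("SmoothingKernel: FWHM %g mm (sigma %.4f mm, cut at %g sigma)\n",
              object@fwhmMm, object@sigmaMm, object@truncationSigmas))
})

## ---------------------------------------------------------------------------
## ThresholdedNetwork
## ---------------------------------------------------------------------------

#' Density-thresholded weighted correlation network
#'
#' Holds the weighted adjacency restricted to the m strongest links (by
#' signed weight), where m = round(d * N(N-1)/2) for the requested density
#' d. Retained links keep their correlation weights; removed entries are 0.
#'
#' @slot density requested link density in (0, 1].
#' @slot weights symmetric numeric matrix with zero diagonal; non-retained
#'   entries are exactly 0.
#' @slot nodeIds integer ROI ids, parallel to the matrix rows.
#' @slot nRetained number of retained undirected links m.
#' @export
setClass("ThresholdedNetwork",
  representation(density = "numeric", weights = "matrix",
                 nodeIds = "integer", nRetained = "integer"))

setValidity("ThresholdedNetwork", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 0)))
    return("weights must be exactly symmetric")
  if (any(diag(w) != 0)) return("diagonal must be exactly zero")
  if (sum(w[upper.tri(w)] != 0) != object@nRetained)
    return("nRetained inconsistent with the weight matrix")
  if (object@density <= 0 || object@density > 1)
    return("density must be in (0, 1]")
  TRUE
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf(
    "ThresholdedNetwork: %d nodes, %d links retained (density %.4g)\n",
    nrow(object@weights), object@nRetained, object@density))
})
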