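#' @import methods
#' @importFrom stats cor cor.test var sd rnorm
#' @importFrom utils write.table head combn packageVersion
NULL

#' Voxel grid coordinates
#'
#' 0-based integer grid coordinates (columns \code{x}, \code{y}, \code{z}),
#' one row per voxel, in the object's voxel order.
#'
#' @param x a \linkS4class{VoxelTimeSeries}.
#' @return An integer matrix with columns \code{x}, \code{y}, \code{z}.
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' Voxel edge lengths in millimetres
#' @param x a \linkS4class{VoxelTimeSeries}.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
setGeneric("voxelSizeMm", function(x) standardGeneric("voxelSizeMm"))

#' ROI identifiers
#' @param x a \linkS4class{Parcellation} or \linkS4class{RoiTimeSeries}.
#' @return Sorted integer vector of positive ROI labels.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' ROI sizes (voxel counts)
#' @param x a \linkS4class{Parcellation} or \linkS4class{RoiTimeSeries}.
#' @return Named integer vector, one entry per ROI.
#' @export
setGeneric("roiSizes", function(x) standardGeneric("roiSizes"))

#' Number of time points
#' @param x a \linkS4class{VoxelTimeSeries} or \linkS4class{RoiTimeSeries}.
#' @return Integer scalar.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Remove the least-squares linear trend from every series
#'
#' Subtracts the ordinary least-squares straight-line fit (intercept and
#' slope against the time index) from each row, so every output series has
#' zero mean and zero linear trend.
#'
#' @param x a numeric matrix (series in rows), a
#'   \linkS4class{VoxelTimeSeries} or a \linkS4class{RoiTimeSeries} with at
#'   least 3 time points.
#' @return An object of the same class with detrended series.
#' @examples
#' detrendLinear(rbind(1:4, c(2, 2, 2, 2)))  # both rows become zero
#' @export
setGeneric("detrendLinear", function(x) standardGeneric("detrendLinear"))
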