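## Synthetic BOLD generator: per-ROI shared latent components plus
## voxel-unique components, with known population correlation structure.
##
## Every voxel i in ROI I follows
##   x_i(t) = sqrt(a_I) g_I(t) + sqrt(b) h(t) + sqrt(1 - a_I - b) eps_i(t)
## with unit-variance latents g_I (cross-correlated according to R), an
## optional brain-wide latent h, and voxel-unique noise eps_i. The implied
## population correlations are
##   same ROI:        a_I + b
##   voxels of I, J:  sqrt(a_I a_J) R_IJ + b
## which makes every downstream statistic checkable in closed form.

#' Specification of a synthetic BOLD dataset
#'
#' @slot roiSizes integer voxel counts per ROI.
#' @slot nTimepoints number of time points T.
#' @slot sharedFraction per-ROI variance fraction a_I of the ROI-shared
#'   latent, in [0, 1].
#' @slot globalFraction variance fraction b of a brain-wide latent shared by
#'   every voxel, in [0, 1]; a_I + b <= 1 is required.
#' @slot latentCorrelation symmetric unit-diagonal positive-semidefinite
#'   matrix R of correlations among the ROI latents.
#' @slot seed master seed; sub-streams are derived for the joint latent
#'   draw, the global latent, and each ROI's noise, so resizing one ROI
#'   does not reshuffle the others.
#' @slot gridShape integer triple: the voxel grid in which ROIs are placed
#'   as contiguous axis-aligned blocks.
#' @slot ar optional AR(1) coefficient applied to all latent and noise
#'   series (unit marginal variance preserved); default 0, i.e. serially
#'   independent Gaussian.
#' @slot voxelSizeMm voxel edge lengths in mm for the embedded grid.
#' @export
setClass("SyntheticSpec",
  representation(roiSizes = "integer", nTimepoints = "integer",
                 sharedFraction = "numeric", globalFraction = "numeric",
                 latentCorrelation = "matrix", seed = "integer",
                 gridShape = "integer", ar = "numeric",
                 voxelSizeMm = "numeric"))

setValidity("SyntheticSpec", function(object) {
  nr <- length(object@roiSizes)
  if (nr < 1L || any(object@roiSizes < 1L))
    return("roiSizes must be positive integers")
  if (object@nTimepoints < 2L)
    return("nTimepoints must be at least 2")
  a <- object@sharedFraction
  b <- object@globalFraction
  if (length(a) != nr || any(a < 0) || any(a > 1))
    return("sharedFraction must be one value in [0,1] per ROI")
  if (length(b) != 1L || b < 0 || b > 1)
    return("globalFraction must be a single value in [0,1]")
  if (any(a + b > 1 + 1e-12))
    return("sharedFraction + globalFraction must not exceed 1")
  R <- object@latentCorrelation
  if (!is.matrix(R) || nrow(R) != nr || ncol(R) != nr)
    return("latentCorrelation must be an n_rois x n_rois matrix")
  if (max(abs(R - t(R))) > 1e-12)
    return("latentCorrelation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-12)
    return("latentCorrelation must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12))
    return("latentCorrelation entries must lie in [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    return("latentCorrelation must be positive semidefinite")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be a positive integer triple")
  if (sum(object@roiSizes) > prod(object@gridShape))
    return(sprintf("grid capacity %d is too small for %d ROI voxels",
                   prod(object@gridShape), sum(object@roiSizes)))
  if (abs(object@ar) >= 1)
    return("ar must lie in (-1, 1)")
  TRUE
})

## Near-cubic factor triple of n, oriented to the grid axes (largest block
## dimension on the largest grid axis); NULL when no triple fits.
.blockDims <- function(n, gridShape) {
  divs <- which(n %% seq_len(n) == 0)
  best <- NULL
  for (d1 in divs) {
    m <- n / d1
    for (d2 in which(m %% seq_len(m) == 0)) {
      dims <- sort(c(d1, d2, m / d2), decreasing = TRUE)
      if (!is.null(gridShape) &&
          any(dims > sort(gridShape, decreasing = TRUE))) next
      if (is.null(best) || dims[1] < best[1] ||
          (dims[1] == best[1] && sum(dims) < sum(best))) best <- dims
    }
  }
  if (is.null(best)) return(NULL)
  if (is.null(gridShape)) return(as.integer(best))
  out <- integer(3)
  out[order(gridShape, decreasing = TRUE)] <- as.integer(best)
  out
}

#' Create a synthetic dataset specification
#'
#' @param roiSizes voxel counts N_I, one per ROI.
#' @param nTimepoints number of time points T.
#' @param sharedFraction variance fraction a_I of the ROI-shared latent;
#'   recycled across ROIs.
#' @param globalFraction variance fraction b of the brain-wide latent.
#' @param latentCorrelation correlation matrix R of the ROI latents
#'   (default: identity).
#' @param seed master seed for all random draws.
#' @param gridShape voxel grid as an integer triple; by default a grid just
#'   large enough to stack near-cubic ROI blocks along the first axis.
#' @param ar AR(1) coefficient of latents and noise (default 0).
#' @param voxelSizeMm voxel edge lengths in mm.
#' @return A validated \linkS4class{SyntheticSpec}.
#' @examples
#' syntheticSpec(c(8, 8), 100, sharedFraction = 0.3,
#'               latentCorrelation = matrix(c(1, 2/3, 2/3, 1), 2))
#' @export
syntheticSpec <- function(roiSizes, nTimepoints, sharedFraction = 0.3,
                          globalFraction = 0, latentCorrelation = NULL,
                          seed = 1L, gridShape = NULL, ar = 0,
                          voxelSizeMm = c(4, 4, 4)) {
  roiSizes <- as.integer(roiSizes)
  nr <- length(roiSizes)
  sharedFraction <- rep_len(as.numeric(sharedFraction), nr)
  if (is.null(latentCorrelation)) latentCorrelation <- diag(nr)
  if (is.null(gridShape)) {
    dims <- lapply(roiSizes, .blockDims, gridShape = NULL)
    gridShape <- c(sum(vapply(dims, `[`, integer(1), 1L)),
                   max(vapply(dims, `[`, integer(1), 2L)),
                   max(vapply(dims, `[`, integer(1), 3L)))
  }
  new("SyntheticSpec", roiSizes = roiSizes,
      nTimepoints = as.integer(nTimepoints),
      sharedFraction = sharedFraction,
      globalFraction = as.numeric(globalFraction),
      latentCorrelation = as.matrix(latentCorrelation),
      seed = as.integer(seed), gridShape = as.integer(gridShape),
      ar = as.numeric(ar), voxelSizeMm = as.numeric(voxelSizeMm))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d ROIs (%d voxels) x %d time points on a %s grid\n",
    length(object@roiSizes), sum(object@roiSizes), object@nTimepoints,
    paste(object@gridShape, collapse = " x ")))
  cat(sprintf("  shared fractions a: %s;  global fraction b: %g\n",
              paste(signif(object@sharedFraction, 3), collapse = ", "),
              object@globalFraction))
})

#' Place the ROIs of a synthetic spec as contiguous blocks
#'
#' Each ROI occupies a contiguous axis-aligned block of exactly N_I voxels
#' in the spec's grid; blocks are disjoint and placed greedily at the first
#' free anchor in lexicographic order, so placement is deterministic.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{Parcellation} on the spec's grid.
#' @examples
#' generateParcellation(syntheticSpec(c(8, 8), 50, gridShape = c(4, 4, 4)))
#' @export
generateParcellation <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  g <- spec@gridShape
  lab <- array(0L, g)
  for (r in seq_along(spec@roiSizes)) {
    n <- spec@roiSizes[r]
    dims <- .blockDims(n, g)
    placed <- FALSE
    if (!is.null(dims)) {
      for (ax in seq_len(g[1] - dims[1] + 1L)) {
        for (ay in seq_len(g[2] - dims[2] + 1L)) {
          for (az in seq_len(g[3] - dims[3] + 1L)) {
            xi <- ax:(ax + dims[1] - 1L)
            yi <- ay:(ay + dims[2] - 1L)
            zi <- az:(az + dims[3] - 1L)
            if (all(lab[xi, yi, zi] == 0L)) {
              lab[xi, yi, zi] <- r
              placed <- TRUE
            }
            if (placed) break
          }
          if (placed) break
        }
        if (placed) break
      }
    }
    if (!placed)
      stop(sprintf("grid %s is too small to place ROI %d (%d voxels)",
                   paste(g, collapse = "x"), r, n))
  }
  Parcellation(lab)
}

## One unit-variance series matrix (n series x T), optionally AR(1) with
## unit marginal variance.
.unitSeries <- function(n, nT, ar) {
  if (ar == 0) return(matrix(rnorm(n * nT), n, nT))
  x <- matrix(0, n, nT)
  x[, 1L] <- rnorm(n)
  sc <- sqrt(1 - ar^2)
  for (t in 2:nT) x[, t] <- ar * x[, t - 1L] + sc * rnorm(n)
  x
}

#' Generate voxel time series from a synthetic spec
#'
#' Draws the ROI latents jointly with cross-correlation R (via the
#' symmetric eigen square root of R), the optional global latent, and
#' voxel-unique noise, and mixes them with the variance-fraction weights of
#' the spec. Separate sub-seeds per component make the draw reproducible
#' and stable under changes to other ROIs' sizes.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param parcellation the matching \linkS4class{Parcellation}; defaults to
#'   \code{generateParcellation(spec)}.
#' @return A \linkS4class{VoxelTimeSeries} covering the labeled voxels.
#' @examples
#' spec <- syntheticSpec(c(8, 8), 100, sharedFraction = c(1, 0.5))
#' vts <- generateVoxelTimeSeries(spec)
#' @export
generateVoxelTimeSeries <- function(spec,
                                    parcellation = generateParcellation(spec)) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  nr <- length(spec@roiSizes)
  nT <- spec@nTimepoints
  seeds <- subSeeds(spec@seed, 2L + nr)

  R <- spec@latentCorrelation
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nr)
  Z <- withSeed(seeds[1L], .unitSeries(nr, nT, spec@ar))    # nr x T
  G <- L %*% Z                                              # correlated latents
  h <- withSeed(seeds[2L], .unitSeries(1L, nT, spec@ar))[1L, ]

  lab <- parcellation@labels
  idx <- which(lab > 0L)
  coords <- arrayInd(idx, dim(lab)) - 1L
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  idx <- idx[ord]
  coords <- coords[ord, , drop = FALSE]
  labvec <- lab[idx]

  data <- matrix(0, length(idx), nT)
  b <- spec@globalFraction
  for (r in seq_len(nr)) {
    rows <- which(labvec == parcellation@roiIds[r])
    a <- spec@sharedFraction[r]
    eps <- withSeed(seeds[2L + r], .unitSeries(length(rows), nT, spec@ar))
    data[rows, ] <- sqrt(a) * matrix(G[r, ], length(rows), nT, byrow = TRUE) +
      sqrt(b) * matrix(h, length(rows), nT, byrow = TRUE) +
      sqrt(1 - a - b) * eps
  }
  VoxelTimeSeries(data, coords, voxelSizeMm = spec@voxelSizeMm)
}

#' Closed-form population statistics of a synthetic spec
#'
#' The oracle for every downstream stage: per ROI, the population
#' consistency \eqn{\phi^* = a_I + b}; per ROI pair, the population
#' voxel-level correlation \eqn{C^*_{vox} = \sqrt{a_I a_J} R_{IJ} + b} and
#' the population ROI-level correlation
#' \deqn{C^*_{ROI} = \frac{\sqrt{a_I a_J} R_{IJ} + b}
#'   {\sqrt{(a_I + b + (1-a_I-b)/N_I)(a_J + b + (1-a_J-b)/N_J)}}.}
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A list with data frames \code{roi} (roi_id, size, phi) and
#'   \code{pairs} (roi_i, roi_j, mean_consistency, c_vox, c_roi).
#' @examples
#' s <- syntheticSpec(c(150, 150), 5000, sharedFraction = 0.3,
#'                    latentCorrelation = matrix(c(1, 2/3, 2/3, 1), 2))
#' expectedStatistics(s)$pairs  # c_vox = 0.2, c_roi ~ 0.656
#' @export
expectedStatistics <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  a <- spec@sharedFraction
  b <- spec@globalFraction
  n <- spec@roiSizes
  nr <- length(n)
  roi <- data.frame(roi_id = seq_len(nr), size = n,
                    phi = ifelse(n >= 2L, a + b, NA_real_))
  pr <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  i <- pr[, 1L]; j <- pr[, 2L]
  cvox <- sqrt(a[i] * a[j]) * spec@latentCorrelation[pr] + b
  den <- sqrt((a[i] + b + (1 - a[i] - b) / n[i]) *
              (a[j] + b + (1 - a[j] - b) / n[j]))
  pairs <- data.frame(roi_i = i, roi_j = j,
                      mean_consistency = (a[i] + a[j]) / 2 + b,
                      c_vox = cvox, c_roi = cvox / den)
  list(roi = roi, pairs = pairs[order(pairs$roi_i, pairs$roi_j), ])
}

#' Write a synthetic dataset to NIfTI files with a JSON sidecar
#'
#' Emits the 4-D voxel series and the 3-D label volume as NIfTI-1 files on
#' an identity (RAS) grid with the spec's voxel size, plus the spec itself
#' as JSON, so the file-based pipeline can be exercised end to end.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, a named list of the three file paths
#'   (\code{bold}, \code{labels}, \code{spec}).
#' @export
writeSyntheticDataset <- function(spec, dir, prefix = "synthetic") {
  stopifnot(is(spec, "SyntheticSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parc <- generateParcellation(spec)
  vts <- generateVoxelTimeSeries(spec, parc)
  g <- spec@gridShape
  arr <- array(0, c(g, spec@nTimepoints))
  cc <- voxelCoords(vts) + 1L
  for (t in seq_len(spec@nTimepoints))
    arr[cbind(cc, t)] <- assay(vts)[, t]
  bold <- RNifti::asNifti(arr)
  RNifti::pixdim(bold) <- c(spec@voxelSizeMm, 1)
  labels <- RNifti::asNifti(array(as.numeric(parc@labels), g))
  RNifti::pixdim(labels) <- spec@voxelSizeMm
  paths <- list(bold = file.path(dir, paste0(prefix, "_bold.nii")),
                labels = file.path(dir, paste0(prefix, "_labels.nii")),
                spec = file.path(dir, paste0(prefix, "_spec.json")))
  RNifti::writeNifti(bold, paths$bold)
  RNifti::writeNifti(labels, paths$labels)
  jsonlite::write_json(
    list(roi_sizes = spec@roiSizes, n_timepoints = spec@nTimepoints,
         shared_fraction = spec@sharedFraction,
         global_fraction = spec@globalFraction,
         latent_correlation = spec@latentCorrelation, seed = spec@seed,
         grid_shape = spec@gridShape, ar = spec@ar,
         voxel_size_mm = spec@voxelSizeMm),
    paths$spec, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
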