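## Weighted correlation networks: full adjacency, density thresholding,
## degree/strength, and the consistency-centrality relation.

#' Full weighted adjacency of ROI-level correlations
#'
#' Zero-lag Pearson correlations between all ROI time-series pairs, with
#' the diagonal removed (set to zero). Negative correlations are retained;
#' an N-node matrix carries N(N-1)/2 independent off-diagonal values.
#'
#' @param rts a \linkS4class{RoiTimeSeries} whose rows all have nonzero
#'   variance.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ROI
#'   ids.
#' @export
buildAdjacency <- function(rts) {
  stopifnot(is(rts, "RoiTimeSeries"))
  m <- assay(rts)
  const <- which(rowVariance(m) == 0)
  if (length(const))
    stop(sprintf("constant ROI series: %s",
                 paste(roiIds(rts)[const], collapse = ", ")))
  A <- cor(t(m))
  diag(A) <- 0
  dimnames(A) <- list(roiIds(rts), roiIds(rts))
  A
}

#' Threshold an adjacency matrix to a target link density
#'
#' Keeps the m = round(d * N(N-1)/2) strongest links ranked by signed
#' weight (so negative correlations drop out first at low densities);
#' retained links keep their weights, everything else is set to zero.
#' Ties at the cutoff are broken deterministically by (i, j) node-pair
#' order and logged via a message. Rounding is half-up, so d = 0.25 on 6
#' links keeps round(1.5) = 2.
#'
#' @param A symmetric numeric matrix with zero diagonal (see
#'   \code{\link{buildAdjacency}}).
#' @param d target density in (0, 1].
#' @return A \linkS4class{ThresholdedNetwork}.
#' @export
thresholdToDensity <- function(A, d) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  if (max(abs(A - t(A))) > 0) stop("A must be symmetric")
  if (any(diag(A) != 0)) stop("A must have a zero diagonal")
  if (d <= 0 || d > 1) stop("density must be in (0, 1]")
  N <- nrow(A)
  M <- N * (N - 1) / 2
  m <- as.integer(roundHalfUp(d * M))
  if (m < 1L) stop(sprintf("density %g keeps zero links on %d nodes", d, N))
  ut <- which(upper.tri(A), arr.ind = TRUE)
  w <- A[ut]
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(m)]
  if (m < M && w[ord[m]] == w[ord[m + 1L]])
    message(sprintf(
      "thresholdToDensity: tie at the cutoff weight %g broken by node order",
      w[ord[m]]))
  W <- matrix(0, N, N, dimnames = dimnames(A))
  ki <- ut[keep, , drop = FALSE]
  W[ki] <- w[keep]
  W[ki[, c(2L, 1L), drop = FALSE]] <- w[keep]
  ids <- if (!is.null(rownames(A))) as.integer(rownames(A)) else seq_len(N)
  new("ThresholdedNetwork", density = d, weights = W,
      nodeIds = ids, nRetained = m)
}

#' Degree and strength of every node in a thresholded network
#'
#' Degree k is the number of retained links at a node; strength s is the
#' sum of their weights. Isolated nodes get k = 0, s = 0.
#'
#' @param net a \linkS4class{ThresholdedNetwork}.
#' @return A data frame: roi_id, degree, strength.
#' @export
degreeAndStrength <- function(net) {
  stopifnot(is(net, "ThresholdedNetwork"))
  W <- net@weights
  data.frame(roi_id = net@nodeIds,
             degree = as.integer(colSums(W != 0)),
             strength = colSums(W))
}

#' The link-density grid emphasizing sparse networks
#'
#' Densities 0.25\% through 5\% in fine steps, then 10, 15, 20\%: the grid
#' under which the consistency-centrality relation is evaluated.
#'
#' @return Numeric vector of 15 densities (as fractions).
#' @export
defaultDensityGrid <- function() {
  c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 10, 15, 20) / 100
}

#' Relation between ROI consistency and node centrality across densities
#'
#' For every density in the grid the adjacency is thresholded and the
#' Pearson correlation (with p) of consistency against degree and against
#' strength is computed, together with consistency-binned mean degree and
#' strength curves. Degenerate cases (constant k, e.g. the full network
#' where every k = N-1, or constant phi) are flagged as undefined rather
#' than reported as spurious values.
#'
#' @param consistencies data frame from \code{\link{roiConsistency}}.
#' @param A adjacency matrix from \code{\link{buildAdjacency}}.
#' @param densities density grid (default \code{\link{defaultDensityGrid}}).
#' @param nBins number of consistency bins for the binned curves.
#' @return A list: correlations (data frame density, r_degree, p_degree,
#'   r_strength, p_strength, defined_degree, defined_strength) and binned
#'   (data frame with per-density consistency-binned mean k and s).
#' @export
consistencyCentralityRelation <- function(consistencies, A,
                                          densities = defaultDensityGrid(),
                                          nBins = 10) {
  phi <- consistencies$phi[match(as.integer(rownames(A)),
                                 consistencies$roi_id)]
  ok0 <- !is.na(phi)
  corOrNA <- function(x, y) {
    ok <- ok0 & !is.na(y)
    if (sum(ok) > 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      ct <- cor.test(x[ok], y[ok])
      list(r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
    } else list(r = NA_real_, p = NA_real_, defined = FALSE)
  }
  cors <- list(); bins <- list()
  for (d in densities) {
    ds <- degreeAndStrength(thresholdToDensity(A, d))
    ck <- corOrNA(phi, ds$degree)
    cs <- corOrNA(phi, ds$strength)
    cors[[length(cors) + 1L]] <- data.frame(
      density = d, r_degree = ck$r, p_degree = ck$p,
      r_strength = cs$r, p_strength = cs$p,
      defined_degree = ck$defined, defined_strength = cs$defined)
    tb <- data.frame(phi = phi[ok0], degree = ds$degree[ok0],
                     strength = ds$strength[ok0])
    bk <- relationBinned(tb, "phi", "degree", nBins)
    bs <- relationBinned(tb, "phi", "strength", nBins)
    bins[[length(bins) + 1L]] <- data.frame(
      density = d, bin = bk$bin, phi_low = bk$x_low, phi_high = bk$x_high,
      n = bk$n, mean_degree = bk$mean_y, mean_strength = bs$mean_y)
  }
  list(correlations = do.call(rbind, cors), binned = do.call(rbind, bins))
}

#' Write the retained edges of a thresholded network as TSV
#'
#' @param net a \linkS4class{ThresholdedNetwork}.
#' @param path output file (columns i, j, weight).
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path) {
  W <- net@weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  df <- data.frame(i = net@nodeIds[ut[, 1L]], j = net@nodeIds[ut[, 2L]],
                   weight = W[ut])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
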