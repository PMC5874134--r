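## The six-link weight fixture used throughout: weights on 4 nodes.
fixtureAdjacency <- function() {
  A <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  w <- rbind(c(1, 2, 0.9), c(2, 3, 0.7), c(1, 3, 0.5),
             c(3, 4, 0.3), c(1, 4, 0.1), c(2, 4, -0.2))
  A[w[, 1:2]] <- w[, 3]
  A[w[, 2:1]] <- w[, 3]
  A
}

test_that("the adjacency holds all pairwise ROI correlations with a zero
           diagonal", {
  set.seed(71)
  m <- matrix(rnorm(4 * 50), 4)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m),
    rowData = S4Vectors::DataFrame(roi_id = 1:4, size = rep(2L, 4)))
  rts <- new("RoiTimeSeries", se)
  A <- buildAdjacency(rts)
  expect_identical(diag(A), c("1" = 0, "2" = 0, "3" = 0, "4" = 0))
  expect_identical(sum(upper.tri(A)), 6L)
  expect_equal(A[1, 2], cor(m[1, ], m[2, ]))
  expect_equal(A, t(A))

  ## identical rows give all off-diagonal weights 1
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m[c(1, 1, 1), ]),
    rowData = S4Vectors::DataFrame(roi_id = 1:3, size = rep(1L, 3)))
  A2 <- buildAdjacency(new("RoiTimeSeries", se2))
  expect_equal(unname(A2[upper.tri(A2)]), rep(1, 3))

  ## a constant ROI series is an error naming the ROI
  m3 <- m; m3[2, ] <- 5
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m3),
    rowData = S4Vectors::DataFrame(roi_id = 1:4, size = rep(2L, 4)))
  expect_error(buildAdjacency(new("RoiTimeSeries", se3)), "2")
})

test_that("adjacency of synthetic data approaches the population c_roi", {
  nr <- 4
  R <- matrix(0.5, nr, nr); diag(R) <- 1
  spec <- syntheticSpec(rep(50, nr), 3000, sharedFraction = 0.4,
                        latentCorrelation = R, seed = 73)
  parc <- generateParcellation(spec)
  rts <- roiAverage(generateVoxelTimeSeries(spec, parc), parc)
  A <- buildAdjacency(rts)
  e <- expectedStatistics(spec)$pairs
  tol <- 3 / sqrt(3000 - 3)
  for (k in seq_len(nrow(e)))
    expect_lt(abs(atanh(A[e$roi_i[k], e$roi_j[k]]) - atanh(e$c_roi[k])),
              tol)
})

test_that("density thresholding keeps the m strongest signed links with
           the documented rounding", {
  A <- fixtureAdjacency()

  ## d = 1 retains everything, including the negative link
  full <- thresholdToDensity(A, 1)
  expect_identical(full@nRetained, 6L)
  expect_equal(full@weights[2, 4], -0.2)

  ## d = 0.5: m = 3, the three strongest by signed weight
  half <- thresholdToDensity(A, 0.5)
  expect_identical(half@nRetained, 3L)
  expect_equal(half@weights[1, 2], 0.9)
  expect_equal(half@weights[2, 3], 0.7)
  expect_equal(half@weights[1, 3], 0.5)
  expect_identical(sum(half@weights != 0), 6L)   # symmetric storage

  ## d = 0.25: m = round(1.5) = 2 under round-half-up
  quarter <- thresholdToDensity(A, 0.25)
  expect_identical(quarter@nRetained, 2L)
  expect_equal(sort(quarter@weights[quarter@weights != 0]),
               rep(c(0.7, 0.9), each = 2))

  expect_error(thresholdToDensity(A, 0), "density")
  expect_error(thresholdToDensity(A, 0.01), "zero links")
})

test_that("degree and strength count and sum the retained links", {
  A <- fixtureAdjacency()
  half <- degreeAndStrength(thresholdToDensity(A, 0.5))
  expect_identical(half$degree, c(2L, 2L, 2L, 0L))
  expect_equal(half$strength, c(0.9 + 0.5, 0.9 + 0.7, 0.7 + 0.5, 0))

  full <- degreeAndStrength(thresholdToDensity(A + 0 * A, 1))
  expect_identical(full$degree, rep(3L, 4))
})

test_that("thresholding honours its structural invariants on random
           matrices", {
  set.seed(79)
  N <- 25   # large enough that the sparsest grid density keeps >= 1 link
  M <- N * (N - 1) / 2
  B <- matrix(rnorm(N * N), N)
  A <- cor(B)
  diag(A) <- 0
  dimnames(A) <- list(1:N, 1:N)
  grid <- defaultDensityGrid()
  prevDeg <- rep(0L, N)
  for (d in grid) {
    net <- thresholdToDensity(A, d)
    m <- floor(d * M + 0.5)
    expect_identical(net@nRetained, as.integer(m))
    ds <- degreeAndStrength(net)
    expect_identical(sum(ds$degree), 2L * net@nRetained)
    expect_true(all(ds$degree >= prevDeg))     # monotone in density
    prevDeg <- ds$degree
    if (all(net@weights[net@weights != 0] > 0))
      expect_true(all(ds$strength[ds$degree > 0] > 0))
  }

  ## permutation equivariance: relabeling nodes relabels the retained set
  perm <- sample(N)
  Ap <- A[perm, perm]
  dimnames(Ap) <- list(1:N, 1:N)
  n1 <- thresholdToDensity(A, 0.1)
  n2 <- thresholdToDensity(Ap, 0.1)
  expect_equal(unname(n2@weights), unname(n1@weights[perm, perm]))
})

test_that("the consistency-centrality relation flags degenerate densities
           and finds the expected positive association", {
  ## heterogeneous shared fractions, homogeneous latent correlation:
  ## high-a ROIs carry the strongest ROI-level links
  nr <- 10
  R <- matrix(0.45, nr, nr); diag(R) <- 1
  spec <- syntheticSpec(rep(30, nr), 1200,
                        sharedFraction = seq(0.1, 0.85, length.out = nr),
                        latentCorrelation = R, seed = 83)
  parc <- generateParcellation(spec)
  vts <- generateVoxelTimeSeries(spec, parc)
  cons <- roiConsistency(vts, parc)
  A <- buildAdjacency(roiAverage(vts, parc))
  rel <- consistencyCentralityRelation(cons, A,
                                       densities = c(0.1, 0.25, 1),
                                       nBins = 4)
  low <- rel$correlations[rel$correlations$density == 0.1, ]
  expect_true(low$defined_strength)
  expect_gt(low$r_strength, 0)
  ## at d = 1 every degree is N - 1: flagged undefined, not reported
  fullRow <- rel$correlations[rel$correlations$density == 1, ]
  expect_false(fullRow$defined_degree)
  expect_true(is.na(fullRow$r_degree))
  ## binned curves exist for every density
  expect_identical(sort(unique(rel$binned$density)), c(0.1, 0.25, 1))
})
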