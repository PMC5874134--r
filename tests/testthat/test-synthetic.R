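test_that("ROIs are placed as disjoint contiguous blocks of the exact size", {
  p1 <- generateParcellation(syntheticSpec(1, 10, gridShape = c(1, 1, 1)))
  expect_identical(p1@labels[1, 1, 1], 1L)
  expect_identical(roiSizes(p1), c("1" = 1L))

  p2 <- generateParcellation(syntheticSpec(c(8, 8), 10,
                                           gridShape = c(4, 4, 4)))
  expect_identical(unname(roiSizes(p2)), c(8L, 8L))
  expect_identical(sum(p2@labels == 0L), 48L)
  ## each ROI is a 2x2x2 axis-aligned block: its bounding box has 8 cells
  for (id in 1:2) {
    idx <- which(p2@labels == id, arr.ind = TRUE)
    expect_identical(unname(apply(idx, 2, function(v) diff(range(v)) + 1)),
                     c(2, 2, 2))
  }
  ## disjointness by enumeration: every voxel carries exactly one label
  expect_identical(sum(p2@labels == 1L) + sum(p2@labels == 2L), 16L)
})

test_that("requesting more voxels than the grid holds is a capacity error", {
  expect_error(syntheticSpec(c(33, 32), 10, gridShape = c(4, 4, 4)),
               "capacity")
  ## a fitting total that cannot be placed as blocks is also an error
  expect_error(generateParcellation(
    syntheticSpec(c(7, 2), 10, gridShape = c(3, 3, 1))),
    "too small")
})

test_that("variance-fraction parameters control the generated correlations", {
  ## a = 1, b = 0: all voxels of the ROI are identical, phi = 1 exactly
  spec1 <- syntheticSpec(c(5, 5), 50, sharedFraction = c(1, 0.5), seed = 2)
  vts1 <- generateVoxelTimeSeries(spec1)
  parc1 <- generateParcellation(spec1)
  m <- assay(vts1)[parc1@labels[voxelCoords(vts1) + 1L] == 1L, ]
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-12)
  expect_equal(roiConsistency(vts1, parc1, roiId = 1)$phi, 1)

  ## a = 0, b = 0: independent voxels, sample correlations near zero
  spec0 <- syntheticSpec(c(20, 20), 4000, sharedFraction = 0, seed = 5)
  vts0 <- generateVoxelTimeSeries(spec0)
  cm <- cor(t(assay(vts0)))
  expect_lt(max(abs(cm[upper.tri(cm)])), 4 / sqrt(4000 - 3))

  ## a = 0.25, N = 50, T = 2000: sample consistency within 0.25 +/- 0.03
  spec <- syntheticSpec(50, 2000, sharedFraction = 0.25, seed = 9)
  phi <- roiConsistency(generateVoxelTimeSeries(spec),
                        generateParcellation(spec))$phi
  expect_lt(abs(phi - 0.25), 0.03)
})

test_that("generation is bit-identical under a fixed seed and sub-streams
           are stable when another ROI is resized", {
  spec <- syntheticSpec(c(10, 12), 60, sharedFraction = c(0.4, 0.2),
                        seed = 42)
  a <- generateVoxelTimeSeries(spec)
  b <- generateVoxelTimeSeries(spec)
  expect_identical(assay(a), assay(b))

  ## resizing ROI 2 leaves ROI 1's draws untouched
  spec2 <- syntheticSpec(c(10, 20), 60, sharedFraction = c(0.4, 0.2),
                         seed = 42, gridShape = c(30, 2, 1))
  spec1b <- syntheticSpec(c(10, 12), 60, sharedFraction = c(0.4, 0.2),
                          seed = 42, gridShape = c(30, 2, 1))
  v1 <- generateVoxelTimeSeries(spec1b)
  v2 <- generateVoxelTimeSeries(spec2)
  p1 <- generateParcellation(spec1b)
  p2 <- generateParcellation(spec2)
  r1 <- assay(v1)[p1@labels[voxelCoords(v1) + 1L] == 1L, ]
  r2 <- assay(v2)[p2@labels[voxelCoords(v2) + 1L] == 1L, ]
  expect_identical(r1, r2)
})

test_that("closed-form population statistics match their definitions", {
  ## degenerate perfect case
  s1 <- syntheticSpec(c(4, 4), 10, sharedFraction = 1,
                      latentCorrelation = matrix(1, 2, 2))
  e1 <- expectedStatistics(s1)
  expect_equal(e1$roi$phi, c(1, 1))
  expect_equal(e1$pairs$c_vox, 1)
  expect_equal(e1$pairs$c_roi, 1)

  ## a = 0.3, R = 2/3, N = 150: c_vox = 0.2, c_roi = 0.2/(0.3 + 0.7/150)
  s2 <- syntheticSpec(c(150, 150), 100, sharedFraction = 0.3,
                      latentCorrelation = matrix(c(1, 2/3, 2/3, 1), 2))
  e2 <- expectedStatistics(s2)
  expect_equal(e2$pairs$c_vox, 0.2)
  expect_equal(e2$pairs$c_roi, 0.2 / (0.3 + 0.7 / 150))

  ## N -> infinity: c_roi -> 1 while c_vox = a
  s3 <- syntheticSpec(c(100000, 100000), 100, sharedFraction = 0.33,
                      latentCorrelation = matrix(1, 2, 2),
                      gridShape = c(200000, 1, 1))
  e3 <- expectedStatistics(s3)
  expect_equal(e3$pairs$c_vox, 0.33)
  expect_lt(abs(e3$pairs$c_roi - 1), 1e-4)
})

test_that("population c_vox never exceeds the pair's mean consistency", {
  set.seed(123)
  for (k in 1:25) {
    nr <- sample(2:5, 1)
    spec <- syntheticSpec(sample(5:40, nr, replace = TRUE),
                          50, sharedFraction = runif(nr, 0, 0.8),
                          globalFraction = runif(1, 0, 0.2),
                          latentCorrelation = randomCorrMatrix(nr),
                          seed = k)
    e <- expectedStatistics(spec)
    expect_true(all(e$pairs$c_vox <= e$pairs$mean_consistency + 1e-12))
  }
})

test_that("the AR(1) option keeps unit marginal variance and lag-1
           autocorrelation near the coefficient", {
  spec <- syntheticSpec(2, 20000, sharedFraction = 0, ar = 0.6, seed = 8)
  x <- assay(generateVoxelTimeSeries(spec))[1, ]
  expect_lt(abs(var(x) - 1), 0.1)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.6), 0.05)
})

test_that("invalid specs are rejected, not repaired", {
  expect_error(syntheticSpec(5, 10, sharedFraction = 0.8,
                             globalFraction = 0.3), "exceed 1")
  badR <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(syntheticSpec(c(3, 3, 3), 10, latentCorrelation = badR),
               "semidefinite")
  expect_error(syntheticSpec(3, 10, sharedFraction = 1.2), "\\[0,1\\]")
})
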