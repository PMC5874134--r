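test_that("voxel-level correlation averages all cross-ROI pairs", {
  s <- rnorm(100)
  ## all voxels in both ROIs identical: exactly 1
  vts <- lineVts(rbind(s, s, s, s))
  expect_equal(voxelLevelCorrelation(vts, lineParcellation(c(2, 2)), 1, 2),
               1)

  ## single-voxel ROIs with y = -x: exactly -1
  vts2 <- lineVts(rbind(s, -s))
  expect_equal(voxelLevelCorrelation(vts2, lineParcellation(c(1, 1)), 1, 2),
               -1)

  ## I = {[1,2,3],[2,4,6]}, J = {[1,2,3],[3,2,1]}: mean{1,-1,1,-1} = 0
  vts3 <- lineVts(rbind(c(1, 2, 3), c(2, 4, 6), c(1, 2, 3), c(3, 2, 1)))
  expect_equal(voxelLevelCorrelation(vts3, lineParcellation(c(2, 2)), 1, 2),
               0)
  expect_error(voxelLevelCorrelation(vts3, lineParcellation(c(2, 2)), 1, 1),
               "distinct")
})

test_that("voxel-level correlation equals the brute-force cross-block mean", {
  set.seed(31)
  for (k in 1:3) {
    ni <- sample(2:12, 1); nj <- sample(2:12, 1)
    m <- matrix(rnorm((ni + nj) * 25), ni + nj)
    vts <- lineVts(m)
    expect_equal(
      voxelLevelCorrelation(vts, lineParcellation(c(ni, nj)), 1, 2),
      bruteCvox(m[seq_len(ni), , drop = FALSE],
                m[ni + seq_len(nj), , drop = FALSE]),
      tolerance = 1e-12)
  }
})

test_that("ROI-level correlation works on averaged series and flags a
           constant average as undefined", {
  s <- rnorm(50)
  vts <- lineVts(rbind(s, s, -s, -s))
  parc <- lineParcellation(c(2, 2))
  rts <- roiAverage(vts, parc)
  expect_equal(roiLevelCorrelation(rts, 1, 2), -1)

  ## J = {[1,2,3],[3,2,1]} averages to the constant [2,2,2]
  vts2 <- lineVts(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
  rts2 <- roiAverage(vts2, lineParcellation(c(1, 2)))
  expect_warning(r <- roiLevelCorrelation(rts2, 1, 2), "zero-variance")
  expect_true(is.na(r))
})

test_that("the pair table has one row per unordered pair and is stable
           under relabeling", {
  set.seed(41)
  vts <- lineVts(matrix(rnorm(6 * 60), 6))
  parc <- lineParcellation(c(2, 2, 2))
  rts <- roiAverage(vts, parc)
  tbl <- buildPairTable(vts, rts, parc)
  expect_identical(nrow(tbl), 3L)
  expect_identical(tbl$roi_i, c(1L, 1L, 2L))
  expect_false(any(tbl$flag))
  expect_identical(nrow(attr(tbl, "correlations")), 2L)

  ## relabeling ROIs relabels rows but leaves the values untouched
  lab <- lineParcellation(c(2, 2, 2))@labels
  relab <- Parcellation(array(c(3L, 1L, 2L)[lab], dim(lab)))
  rts2 <- roiAverage(vts, relab)
  tbl2 <- buildPairTable(vts, rts2, relab)
  ## pair (1,2) in the original is pair (1,3) after the 1->3, 2->1 map
  orig <- tbl[tbl$roi_i == 1 & tbl$roi_j == 2, c("c_vox", "c_roi")]
  new <- tbl2[tbl2$roi_i == 1 & tbl2$roi_j == 3, c("c_vox", "c_roi")]
  expect_equal(unlist(orig), unlist(new), ignore_attr = TRUE)
})

test_that("c_vox tracks mean consistency more tightly than c_roi when
           shared fractions vary and R is homogeneous", {
  nr <- 9
  R <- matrix(0.4, nr, nr); diag(R) <- 1
  spec <- syntheticSpec(rep(40, nr), 1200,
                        sharedFraction = seq(0.1, 0.9, length.out = nr),
                        latentCorrelation = R, seed = 51)
  parc <- generateParcellation(spec)
  vts <- generateVoxelTimeSeries(spec, parc)
  tbl <- buildPairTable(vts, roiAverage(vts, parc), parc)
  cors <- attr(tbl, "correlations")
  expect_gt(cors$r[cors$metric == "c_vox"],
            cors$r[cors$metric == "c_roi"])
})

test_that("identity-bound check returns exactly the violating pairs", {
  tbl <- data.frame(roi_i = 1:2, roi_j = 2:3,
                    mean_consistency = c(0.2, 0.5),
                    c_vox = c(0.5, 0.4), c_roi = c(0.6, 0.6),
                    flag = FALSE)
  v <- identityBoundCheck(tbl, tolerance = 0)
  expect_identical(nrow(v), 1L)
  expect_identical(v$roi_i, 1L)
  ## correlations are bounded by 1, so tolerance 2 can never flag
  expect_identical(nrow(identityBoundCheck(tbl, tolerance = 2)), 0L)
  expect_error(identityBoundCheck(tbl[0, ]), "empty")
})

test_that("ROI averaging amplifies cross-ROI correlation and the
           amplification saturates", {
  ## closed form: c_roi = c_vox / (a + (1-a)/N) exceeds c_vox, and its
  ## slope in c_vox is constant in R but the gain falls as a rises
  a <- 0.33; N <- 60
  denom <- a + (1 - a) / N
  rGrid <- seq(0.05, 0.3, by = 0.05) / a   # latent correlations in (0, 1)
  spec <- function(r) syntheticSpec(c(N, N), 100, sharedFraction = a,
    latentCorrelation = matrix(c(1, r, r, 1), 2))
  for (r in rGrid) {
    e <- expectedStatistics(spec(r))$pairs
    expect_gt(e$c_roi, e$c_vox)
    expect_equal(e$c_roi, e$c_vox / denom)
  }
  ## saturation: sweeping the shared fraction with R = 1, the gain from
  ## c_vox to c_roi is concave (the closed form flattens as c_vox grows)
  aGrid <- seq(0.05, 0.9, by = 0.05)
  curve <- vapply(aGrid, function(aa) {
    e <- expectedStatistics(syntheticSpec(c(N, N), 100,
      sharedFraction = aa, latentCorrelation = matrix(1, 2, 2)))$pairs
    c(e$c_vox, e$c_roi)
  }, numeric(2))
  expect_true(all(diff(curve[2, ]) / diff(curve[1, ]) > 0))
  expect_true(all(diff(diff(curve[2, ]) / diff(curve[1, ])) < 0))

  ## sampled version: binned mean c_roi exceeds c_vox in every bin
  nr <- 8
  R <- diag(nr)
  rs <- seq(0.2, 0.95, length.out = choose(nr, 2))
  R[upper.tri(R)] <- rs; R <- pmax(R, t(R)); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  R <- if (min(ev) < 1e-6) cov2cor(R + diag(nr) * (1e-3 - min(ev))) else R
  specS <- syntheticSpec(rep(30, nr), 1500, sharedFraction = a,
                         latentCorrelation = R, seed = 61)
  parc <- generateParcellation(specS)
  vts <- generateVoxelTimeSeries(specS, parc)
  tbl <- buildPairTable(vts, roiAverage(vts, parc), parc)
  bins <- relationBinned(tbl, "c_vox", "c_roi", nBins = 4)
  expect_true(all(bins$mean_y >
                  (bins$x_low + bins$x_high) / 2))
})

test_that("relationBinned covers its degenerate and identity cases", {
  tbl <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  one <- relationBinned(tbl, "x", "y", 1)
  expect_equal(one$mean_y, 2.5)
  idb <- relationBinned(tbl, "x", "y", 3)
  expect_true(all(idb$mean_y >= idb$x_low & idb$mean_y <= idb$x_high))
  expect_error(relationBinned(tbl, "x", "y", 0), "nBins")
  expect_error(relationBinned(tbl, "q", "y", 2), "not present")
})
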