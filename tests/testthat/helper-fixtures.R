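suppressPackageStartupMessages(library(SummarizedExperiment))

## VoxelTimeSeries with the given matrix, voxels strung along the x axis.
lineVts <- function(m, voxelSizeMm = c(4, 4, 4)) {
  VoxelTimeSeries(m, cbind(seq_len(nrow(m)) - 1L, 0L, 0L),
                  voxelSizeMm = voxelSizeMm)
}

## Parcellation with consecutive runs of the given sizes along the x axis.
lineParcellation <- function(sizes) {
  lab <- array(rep.int(seq_along(sizes), sizes), c(sum(sizes), 1L, 1L))
  Parcellation(lab)
}

## Brute-force consistency oracle: the ordered-pair double sum
## 1/(N(N-1)) * sum_{i != i'} C(x_i, x_i'), evaluated pair by pair.
bruteConsistency <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + cor(m[i, ], m[j, ])
  tot / (n * (n - 1))
}

## Brute-force voxel-level inter-ROI correlation oracle:
## 1/(N_I N_J) * sum_{i in I} sum_{j in J} C(x_i, x_j).
bruteCvox <- function(mi, mj) {
  tot <- 0
  for (i in seq_len(nrow(mi))) for (j in seq_len(nrow(mj)))
    tot <- tot + cor(mi[i, ], mj[j, ])
  tot / (nrow(mi) * nrow(mj))
}

## Random positive-semidefinite correlation matrix with off-diagonal
## entries damped below `maxAbs`.
randomCorrMatrix <- function(n, maxAbs = 0.8) {
  B <- matrix(rnorm(n * n), n)
  S <- crossprod(B) + diag(n) * 1e-6
  R <- cov2cor(S)
  R <- maxAbs * R + (1 - maxAbs) * diag(n)
  cov2cor(R)
}
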