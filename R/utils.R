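## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's .Random.seed is restored afterwards. seed = NULL runs as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive k reproducible sub-seeds (< 2^31) from one master seed.
subSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

## Row-wise variance of a matrix (denominator n - 1), without apply().
rowVariance <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

## Mean of the strict upper triangle, NA-aware.
upperTriMean <- function(m) {
  v <- m[upper.tri(m)]
  mean(v, na.rm = TRUE)
}

## round-half-up (the documented rounding rule for retained link counts;
## base round() rounds half to even).
roundHalfUp <- function(x) floor(x + 0.5)

## 1-D zero-padded convolution of a 3-D array along one axis with kernel k
## (odd length, centre at (length(k)+1)/2), implemented as shift-and-add.
convolveAxis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(k)) {
    off <- j - r - 1L                      # source offset
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx.dst <- which(ok)
    idx.src <- src[ok]
    if (axis == 1L)
      out[idx.dst, , ] <- out[idx.dst, , ] + k[j] * arr[idx.src, , ]
    else if (axis == 2L)
      out[, idx.dst, ] <- out[, idx.dst, ] + k[j] * arr[, idx.src, ]
    else
      out[, , idx.dst] <- out[, , idx.dst] + k[j] * arr[, , idx.src]
  }
  out
}

## Gaussian taps for one axis given sigma in voxels; returns NULL when the
## kernel degenerates to the identity.
gaussianTaps <- function(sigmaVox, truncationSigmas) {
  r <- ceiling(truncationSigmas * sigmaVox)
  if (!is.finite(r) || r < 1L) return(NULL)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

## Fisher z-scale distance between two correlations.
fisherZDistance <- function(r1, r2) abs(atanh(r1) - atanh(r2))

## Standard error on the Fisher z scale for T time points.
fisherZSe <- function(nTime) 1 / sqrt(nTime - 3)
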