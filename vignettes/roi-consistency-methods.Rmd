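---
title: "ROI consistency and its relation to functional connectivity: methods"
author: "ROIconsistency package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI consistency methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ROIconsistency)
```

## The problem

ROI-level functional brain networks average the BOLD signals of anatomically
grouped voxels into one node signal and correlate these averages. The
approach rests on the assumption that voxels inside an ROI share coherent
dynamics. This package measures that coherence — the *consistency* of an
ROI, the mean Pearson correlation over all distinct within-ROI voxel pairs —
and traces how it propagates into inter-ROI correlations and into node
centrality in density-thresholded networks.

The central statistical phenomenon is amplification by averaging. Write each
voxel of ROI $I$ as

$$x_i = \sqrt{a_I}\, g_I + \sqrt{b}\, h + \sqrt{1 - a_I - b}\,\varepsilon_i,$$

with a unit-variance ROI-shared latent $g_I$, an optional brain-wide latent
$h$ (variance fraction $b$), and voxel-unique noise $\varepsilon_i$. The
population correlation between two voxels of $I$ is $a_I + b$ — the
population consistency $\phi^*_I$. Between voxels of $I$ and $J$ it is
$\sqrt{a_I a_J} R_{IJ} + b$, where $R$ is the correlation of the latents:
the population voxel-level inter-ROI correlation $C^{*}_{vox}$. Averaging
over $N_I$ voxels shrinks the unique variance by $1/N_I$ but leaves the
shared components intact, so the ROI-level correlation becomes

$$C^{*}_{ROI} = \frac{\sqrt{a_I a_J}\,R_{IJ} + b}
 {\sqrt{\left(a_I + b + \tfrac{1-a_I-b}{N_I}\right)
        \left(a_J + b + \tfrac{1-a_J-b}{N_J}\right)}},$$

which approaches $R_{IJ}$-scale values as $N$ grows even when $C^{*}_{vox}$
is small. With $a = 0.3$, $R_{IJ} = 2/3$, $N = 150$ the voxel-level
correlation is $0.2$ while the ROI-level correlation is
$0.2/(0.3 + 0.7/150) \approx 0.656$ — a pair of unremarkable ROIs that looks
strongly connected after averaging. Two exact consequences are worth noting:
$C_{vox} = 1$ iff every series in both ROIs is identical, and the
population bound $C^{*}_{vox} \le (\phi^*_I + \phi^*_J)/2$ (AM–GM with
$|R| \le 1$) — voxel-level correlation never exceeds the pair's mean
consistency, the "identity line" bound that the pair-table check
`identityBoundCheck()` asserts on samples up to sampling noise.

## What the synthetic generator emulates — and what it does not

`syntheticSpec()` / `generateVoxelTimeSeries()` implement exactly the
variance-fraction model above. Design choices:

- **Serially independent Gaussian draws by default.** None of the analyses
  here depend on temporal autocorrelation; an AR(1) coefficient (unit
  marginal variance) is available for sensitivity checks but defaults to 0.
  Consequently Fisher-z standard errors $1/\sqrt{T-3}$ are exact-order
  tolerances for correlation recovery, and tests use 3 such SEs.
- **Correlated latents via the symmetric eigen square root of $R$.** A
  non-positive-semidefinite $R$ is rejected, not repaired: repairing would
  silently change the population statistics the oracle reports.
- **Axis-aligned block ROIs** placed greedily at the first free anchor in
  lexicographic order: the simplest geometry that is still spatially
  contiguous, so smoothing kernels genuinely cross ROI boundaries.
- **Seed sub-streams.** One master seed is split (via one `sample.int`
  draw) into a joint-latent stream, a global-latent stream, and one noise
  stream per ROI, so resizing one ROI does not reshuffle any other ROI's
  draws. Regeneration under a fixed seed is bit-identical.

The generator does *not* emulate hemodynamics, physiological noise spectra,
head motion, or anatomical variation. Passing tests therefore demonstrate
the statistical machinery (estimator correctness, amplification, bound,
calibration) — not that any particular empirical parcellation is good or
bad. On real data, shared artefacts (motion, scanner drift, global signal)
also load on the "shared component" and inflate both consistency and
ROI-level correlations; the model makes no attempt to distinguish shared
signal from shared noise, because the analysis cannot either.

## Pipeline parameters and defaults

- **Low-power voxel exclusion** (`filterLowPowerVoxels`, default fraction
  0.02): removes voxels whose signal power is below 2% of the mean power
  across voxels, the standard edge-of-brain cleanup. "Power" is not defined
  more precisely in common usage; we take the time-series **variance**,
  which is offset-free and matches the intent of removing near-dead voxels.
  The filter runs **after** detrending in the pipeline (the order is
  recorded in the run manifest); with variance as the power measure the
  difference is a linear-trend term only. Re-applying the recorded absolute
  threshold is idempotent.
- **Linear detrending** (`detrendLinear`): ordinary least-squares line per
  series, leaving residuals orthogonal to intercept and trend.
- **Spatial smoothing** (`smoothSpatial`): isotropic Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, FWHM given in mm (typical
  sensitivity grid 5, 8, 12 mm), truncated at 4σ. Boundary handling is
  **mask renormalization**: weights outside the analysis mask are dropped
  and the rest rescaled to sum to 1. Zero-padding instead would leak power
  out of the brain edge and create artefactual consistency gradients; with
  renormalization a spatially constant field is preserved exactly. The
  convolution is separable and applied per axis in voxel units
  (sigma/voxel-size per axis), so anisotropic voxels are handled.
- **Consistency estimation** (`roiConsistency`): raw correlations are
  averaged without Fisher transformation — the measure is *defined* as the
  mean correlation, and transforming first would change it. Zero-variance
  voxels make Pearson undefined; their pairs are skipped, the pair count
  adjusted, and a warning recorded (on filtered data this arises only from
  degenerate input). ROIs with fewer than two usable voxels get `NA`.
- **Within/between distributions** (`withinBetweenDistributions`): all
  same-ROI pairs pooled against all different-ROI pairs, which weights ROIs
  implicitly by pair count. A `pairCap` (default $10^7$) bounds memory by
  uniform seeded subsampling of the reference group.
- **Permutation t test** (`permutationTTest`): pooled-variance two-sample
  t on the observed labeling; labels permuted uniformly;
  $p = (1 + \#\{|t_{perm}| \ge |t_{obs}|\})/(1 + n_{perm})$ with 10,000
  permutations by default. When the total number of labelings is ≤ 20,000
  the test enumerates them exhaustively instead. The add-one smoothing
  keeps $p > 0$ and makes the test mildly conservative; calibration under a
  true null is verified to sit inside binomial bounds at α = 0.05.
- **Size binning** (`consistencyVsSize`): logarithmic size bins (ROI sizes
  span orders of magnitude), per-bin mean/SD of φ, plus the overall
  size–φ Pearson correlation. Pair-level relations (`relationBinned`) use
  equal-width bins over the x variable.
- **Network extraction** (`buildAdjacency`, `thresholdToDensity`): full
  symmetric Pearson adjacency with the diagonal zeroed; negative weights
  retained in the full matrix. Thresholding keeps the
  $m = \mathrm{round}(d\,N(N-1)/2)$ strongest links by **signed** weight —
  at sparse densities this automatically excludes negative correlations —
  and the network stays weighted. Rounding is half-up (so $d$ = 0.25 on 6
  links keeps 2); "remove links below the $1-d$ percentile" is implemented
  as exact top-$m$ selection, the only reading that produces exact densities
  on finite matrices. Ties at the cutoff are broken by node-pair order and
  logged. The default density grid emphasizes sparse networks: 0.25–5% in
  fine steps, then 10, 15, 20%.
- **Centrality relation** (`consistencyCentralityRelation`): per density,
  Pearson r (with p) of φ against degree and strength, plus φ-binned mean
  curves. Degenerate cases (full network: every degree $N-1$) are flagged
  undefined rather than reported.

## Numerical and degenerate-input choices

Coordinates are 0-based voxel indices ordered lexicographically by
(x, y, z); affines are consumed only at NIfTI I/O (the writer emits an
identity-oriented grid with configurable voxel size). Undefined
correlations (constant series, e.g. an averaged ROI series from exactly
cancelling voxels) are reported as missing and excluded from summary
correlations with counts retained, never silently dropped. Probabilistic
atlases must be thresholded to deterministic labels by the user before
reading. Multi-subject work runs the single-subject pipeline per subject;
`poolConsistency` concatenates raw records for pooled distributions and
averages φ per ROI across subjects for tables — pooling pair values, not
subject averages, into distributions.

## Problem sizes used in the shipped tests

The test suite and the reproduction script run entirely on synthetic data
chosen to keep a laptop run short while leaving comfortable statistical
margins: parameter-recovery tests use 40–150 voxels per ROI and 400–5000
time points (tolerance 3 Fisher-z SEs); the identity-bound sweep uses 50
random specs at T = 400; permutation-test calibration uses 1000 null
replicates of two n = 15 samples at 199 permutations; the amplification
experiment uses the 150-voxel, T = 5000 configuration above with 20
replicates. Exact brute-force equivalence (consistency and voxel-level
correlation against the enumerated double sums) is asserted to 1e-12 on
ROIs of up to 12 voxels.

## Known limitations

- The shared/unique-component decomposition is one consistent formalization
  of "voxels share a common component"; real BOLD admits others (multiple
  shared components per ROI, spatially structured noise), and the
  variance-fraction parameterization cannot express them.
- Consistency is blind to *why* voxels correlate; it cannot separate
  functional homogeneity from shared artefact.
- The pipeline deliberately excludes registration, nuisance regression and
  motion handling: it expects preprocessed voxel series and a matching
  label volume.
- Exact voxel-pair enumeration is quadratic in ROI size; the pair cap
  subsamples the between-ROI pool, so at extreme scales the reference
  distribution is an estimate (seed-reproducible).
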