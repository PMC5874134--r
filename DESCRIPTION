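Package: ROIconsistency
Title: Consistency of Regions of Interest in Functional Brain Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the functional homogeneity of fMRI Regions of
    Interest (ROIs) through their consistency, the mean Pearson
    correlation between the time series of their constituent voxels,
    and relates it to voxel-level and ROI-level inter-regional
    correlations and to node centrality (degree, strength) in
    density-thresholded weighted correlation networks. Includes linear
    detrending, low-power voxel exclusion, mask-renormalized Gaussian
    spatial smoothing, NIfTI input/output, a configuration-driven
    pipeline, and a synthetic BOLD generator with shared latent
    components whose closed-form population statistics serve as oracles
    for every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
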