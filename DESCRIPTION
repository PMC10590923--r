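Package: noemri
Title: Nuclear Overhauser Enhancement MRI Z-Spectrum Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for steady-state nuclear Overhauser enhancement
    (NOE) and chemical exchange saturation transfer (CEST) MRI of the mouse
    brain. Provides a lineshape-level synthetic phantom generator for
    single-slice Z-spectrum acquisitions with WASSR field mapping, per-voxel
    B0 correction by spline re-gridding, spatio-spectral SVD (Casorati)
    denoising, NOE magnetization-transfer-ratio and MTR-asymmetry contrasts,
    voxelwise five-pool Lorentzian decomposition of the Z-spectrum (direct
    saturation, semi-solid magnetization transfer, relayed NOE, amide, amine),
    atlas-to-subject registration with fuzzy c-means skull stripping,
    multiscale affine alignment and Demons refinement with nearest-neighbour
    label transfer, and region-of-interest group statistics (linear mixed
    effects, intraclass correlation, per-region ordinary least squares).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    minpack.lm,
    parallel,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
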