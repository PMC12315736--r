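Package: cytoseg
Title: Direct Segmentation of Cortical Cytoarchitectonic Domains from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-free segmentation of cortical cytoarchitectonic domains from
    ultra-high-resolution diffusion MRI. Provides cortical-reference-frame estimation
    (equidistant and equivolumetric depth, radial orientation field), orientation-adaptive
    anisotropic Gaussian denoising of diffusion-weighted volumes, diffusion tensor fitting
    with scalar microstructural maps (FA, MD, AD, RD, and the Gaussian-limit propagator
    metrics PA, RTOP, RTAP, RTPP), per-hemisphere Gaussian mixture model clustering with
    BIC model selection, 3D morphological label refinement, contingency-matrix label
    harmonization across hemispheres via the Kuhn-Munkres assignment algorithm, and
    segmentation scoring. Includes a synthetic two-hemisphere cortical phantom generator
    with known laminar and areal ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
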