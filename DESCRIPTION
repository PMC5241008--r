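Package: tmjfuse
Title: MRI-CBCT Image Fusion and 3D Reconstruction of the
    Temporomandibular Joint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for fusing magnetic resonance and cone-beam computed
    tomography volumes of the temporomandibular joint (TMJ).  Implements
    rigid multimodal registration by maximisation of (normalised) mutual
    information on a joint intensity histogram with Powell's
    conjugate-direction optimiser, inter-slice gap filling and resampling
    for anisotropic MR acquisitions, threshold and contour-based
    segmentation of condyle, glenoid fossa and articular disc, unsmoothed
    marching-tetrahedra surface models with STL import/export, and
    intra-observer reproducibility metrics (symmetric surface distances
    and the Dice similarity index).  A deterministic digital TMJ phantom
    emulating the acquisition geometry (0.25 mm isotropic CBCT; 3 mm MR
    slices with 0.3 mm gaps) supports end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
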