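Package: stenoreg
Title: Coronary Artery Segmentation, 2D/3D Registration and Stenosis
    Localization from Angiograms and CTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments and labels main coronary arteries in 2D X-ray
    angiograms using starlet (isotropic undecimated) wavelet transforms,
    segments and reconstructs labeled 3D coronary arteries from CTA slice
    stacks via Hounsfield-unit tissue classification, Frangi vesselness
    enhancement and slice-to-slice Intersection Tracking, and registers the
    two modalities with a landmark-normalized affine transform to localize a
    stenosis marked on the angiogram in 3D CTA voxel coordinates. Includes a
    synthetic vascular phantom generator with exhaustive ground truth,
    pixel-level evaluation metrics, and a pipeline driver with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
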