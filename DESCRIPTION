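Package: msplane
Title: Automatic Mid-Sagittal Plane Detection in 3D Fetal Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the fetal mid-sagittal plane (MSP) in 3D first-trimester
    ultrasound volumes with a two-stage deep-learning pipeline: a seed-point
    cascade (U-Net with atrous spatial pyramid pooling plus two object-detection
    networks) localises the fetal head centre, and an adversarially trained
    mask generator (WGAN with gradient penalty plus a cross-entropy term)
    produces a 3D plane mask from the cropped head cube.  Includes plane
    geometry utilities (rasterisation, total-least-squares fitting, rigid
    plane-to-plane transforms, oblique slice extraction), a synthetic
    fetal-head phantom generator with known ground-truth planes, the four
    plane-agreement metrics (included angle, coefficient distance, yaw, roll)
    and cohort-level agreement statistics (paired t-test, Bland-Altman), and
    an end-to-end cross-validation pipeline with a command-line interface.
    All networks run on a small built-in neural-network engine (vectorised
    im2col convolutions over BLAS) so the package has no external
    deep-learning dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    RNifti,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
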