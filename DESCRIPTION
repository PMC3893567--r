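Package: voxreg
Title: Parametric Intensity-Based Image Registration with Stochastic
    Gradient Descent and Cohort-Level Template Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A parametric intensity-based registration engine for 2-D and
    3-D scalar images with physical geometry. Implements translation,
    rigid, similarity, affine, cubic B-spline and composite coordinate
    transforms with sparse parameter Jacobians; mean-squared-difference,
    normalized-correlation and mutual-information similarity metrics with
    analytic derivatives evaluated over stochastic sample sets; a
    bending-energy regularizer; recursive-Gaussian multi-resolution
    pyramids; a chunked three-stage resampling pipeline; and the
    cohort-level operations used in morphometry studies: unbiased
    template construction by transformation averaging and inversion,
    multi-atlas label fusion by majority voting, Jacobian-determinant
    modulation of probabilistic tissue maps, and region-wise volume
    features. All functionality is exercisable on deterministic synthetic
    fixtures; no external imaging data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
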