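Package: ctnmqr
Title: Low-Rank Tensor Completion via Core-Tensor Nuclear-Norm
    Minimization with Thin-QR Factor Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Completes missing entries of partially observed dense
    tensors (order three and above) under a low Tucker-rank model.
    Implements the CTNM-QR algorithm: core-tensor nuclear-norm
    minimization under Tucker decomposition, solved by an alternating
    direction method of multipliers (ADMM) with singular-value
    thresholding for the tensor-valued auxiliary variables and thin-QR
    orthonormalization for the factor-matrix updates, avoiding repeated
    singular value decompositions.  Includes exact low-Tucker-rank
    synthetic tensor generators, uniform missing-entry masks, the
    relative squared error (RSE) metric, a reproducible benchmark grid
    runner, readers and writers for PNG images and NIfTI volumes, and a
    command-line interface for completion of images and MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
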