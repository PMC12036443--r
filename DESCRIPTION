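Package: velflow
Title: Diffeomorphic Velocity Flow Models for Spatiotemporal Atlas Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a time-parameterized, regularized velocity field to a
    chronologically ordered series of corresponding point sets, so that a
    diffeomorphic mapping between any two continuous time points in the
    spanned interval is obtained by numerical integration of the optimized
    field.  Includes generalized multilevel B-spline scattered-data
    approximation of vector fields, velocity-field integration and
    displacement-field inversion, logarithmic normalization of developmental
    ages, label-guided point sampling from annotated volumes, virtual
    template construction at intermediate time points, synthetic ground-truth
    flow generators, and a command-line interface.  Fields are exchanged as
    NIfTI-1 vector images with JSON sidecars and point sets as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
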