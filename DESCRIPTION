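Package: amyhist
Title: Separated Gray-Matter Histogram Analysis of Amyloid PET SUVR Images
Version: 0.1.0
Authors@R:
    person("amyhist", "developers", email = "amyhist@example.org",
           role = c("aut", "cre"))
Description: Histogram-based quantification of amyloid PET images. From an
    SUVR (standardized uptake value ratio) brain volume and co-registered
    probabilistic gray-/white-matter maps, the package builds whole-brain,
    gray-matter and white-matter SUVR histograms, computes descriptive
    parameters (bias-corrected skewness, mode-to-mean ratio, excess
    kurtosis), decomposes the gray-matter histogram into two Gaussian
    components by expectation-maximization (muG1, muG2, piG2), estimates
    the white-matter mean (muW), and derives the composite SUVR (ComSUVR)
    against a cerebellar-cortex reference. A three-component forward model
    and a seeded 3-D brain phantom generator allow the whole pipeline to be
    exercised and validated without patient data. Includes minimal NIfTI-1
    volume input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
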