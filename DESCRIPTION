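Package: hsigp
Title: Evolving Wavelength-Interval Feature Extractors for Hyperspectral
    Regression with Strongly Typed Genetic Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating sediment attributes (organic matter
    content, porosity) from field hyperspectral images.  Reads ENVI
    cubes, corrects overexposed white references, calibrates raw counts
    to reflectance, grids quadrats into subregions and removes bright
    shell pixels.  The core is a strongly typed genetic programming
    engine that evolves feature-extraction trees over variable-width
    wavelength intervals, image filters, grey-level co-occurrence
    matrix and histogram texture descriptors, scored by support vector
    regression fitness.  Includes the standard chemometric toolchain
    the method is benchmarked against: SNV and Savitzky-Golay
    pretreatment, SPXY sample-set partitioning, PLSR with RMSECV latent
    variable selection, grid-searched SVR, and the SPA, CARS and
    regression-coefficient wavelength selectors, plus a synthetic scene
    generator with planted absorption bands for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    signal,
    mixOmics,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
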