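Package: pyrocal
Title: Calibration of Plant Chemical Composition from Thermogravimetric
    Pyrolysis Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating differential thermogravimetric (DTG) pyrolysis
    profiles of plant material to chemical component contents. Provides
    preprocessing of raw thermogravimetric traces onto a uniform temperature
    grid, descriptive statistics of composition tables, multivariate
    calibration by partial least squares (NIPALS), support vector regression,
    Gaussian process regression and baseline models, variable-importance-in-
    projection (VIP) screening of characteristic pyrolysis temperature
    intervals with interval-restricted refitting, and a synthetic data
    generator that emulates the statistical structure of tobacco pyrolysis
    studies so the whole analysis is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    kernlab,
    randomForest,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
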