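Package: qsarpt
Title: QSAR Modelling of Placental Transfer from Molecular and
    Chromatographic Peak-Shape Descriptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modelling of human placental clearance indices of bisphenols from
    molecular and chromatographic descriptors.  Computes peak-shape
    descriptors (width at 5 percent height, asymmetry at 4.4 percent,
    tailing factor, relative retention) from chromatographic traces,
    weights descriptors with a backpropagation perceptron and selects
    those above twice the median weight, enumerates uncorrelated
    descriptor combinations by recursive correlation splitting, fits
    weighted multilinear regressions with significance pruning and BIC
    ranking, and validates models with grouped cross-validation and a
    leave-many-out battery (Q2, QLMO2, RMSEC/CV/P, Lin's concordance
    correlation).  Includes a synthetic-study generator (exponentially
    modified Gaussian chromatograms, correlated descriptor blocks,
    replicate clearance indices from a planted linear model) so the whole
    pipeline can be exercised end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
VignetteBuilder: knitr
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    readxl,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
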