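Package: hylai
Title: Hybrid Radiative-Transfer and Machine-Learning Retrieval of Forest Leaf Area Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess hybrid retrieval workflows for forest Leaf Area
    Index (LAI) from multispectral satellite time series. The package builds
    radiative-transfer training databases by Latin hypercube sampling, applies
    additive and multiplicative Gaussian noise contamination, trains six
    machine-learning regression algorithms to invert band reflectance to LAI,
    validates predictions against a terrestrial-laser-scanning plus litter-trap
    reference, runs Sobol total-effect sensitivity analyses of the canopy
    models, and evaluates a full-factorial grid of workflow features (leaf
    prior, radiative-transfer model, noise levels, sun-zenith-angle feature,
    regression algorithm) with ensemble statistics. A synthetic deciduous
    forest world with known ground truth makes every stage testable without
    satellite or field downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    ranger,
    e1071,
    kernlab,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
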