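Package: stemplast
Title: Agent-Based Simulation of Cancer Stem Cell Plasticity and Tumor
    Growth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: On-lattice agent-based simulator of tumor growth driven by
    cancer stem cells with phenotypic plasticity: stochastic
    differentiation and dedifferentiation at division with memorized
    proliferation capacity (a telomere-length proxy). Includes the
    matching branching-process calculus for the extinction probability of
    the stem-cell lineage and its critical plasticity rate, mask-based
    tumor morphometry (circularity, quiescent fraction, boundary-proximal
    stem-cell fraction), a virtual multi-well invasion assay, and
    fractionated radiotherapy under the linear-quadratic survival model,
    together with reproducible cohort experiment runners and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
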