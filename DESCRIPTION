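Package: lesionfc
Title: Lesion-Aware Structural and Functional Brain Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating structural connectome damage to resting-state
    fMRI functional connectivity in lesioned brains. Builds subject-specific
    structural connectomes from template streamlines by virtual tractography
    (removing streamlines that intersect a lesion mask), estimates partial
    correlation with an adaptive graphical lasso that uses the binarized
    structural connectome as a penalty prior, tests edge-wise damage effects
    with gamma generalized linear models under false-discovery-rate control at
    both region and streamline-endpoint level, and compares diffusion
    (mean first passage time), shortest-path (edge betweenness) and direct
    edge-weight models of communication for predicting which edges are
    modulated by damage. A synthetic-cohort generator produces atlases,
    streamline templates, lesions and BOLD-like time series with the planted
    statistical structure the analysis assumes, so the full pipeline runs and
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
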