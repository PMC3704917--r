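Package: lindeconv
Title: Deconvolution of Per-Cell Gene Expression from Overlapping Sorted
    Cell Fractions on an Invariant Lineage
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates gene expression in individual cells from genome-wide
    measurements on overlapping FACS-sorted cell populations ("fractions")
    defined on an invariant cell lineage, as in the C. elegans embryo. The
    measurements form an underdetermined non-negative linear system b = Ax,
    x >= 0, where A is a fractions-by-cells sort matrix. Provides three
    pseudoinverse-family point estimators (naive, constrained, and
    correlation-weighted), expectation-propagation posterior approximation
    with lineage-group summaries, hit-and-run MCMC over the feasible
    polytope with Gelman-Rubin diagnostics, model resolution matrices,
    greedy reporter selection for experiment design, synthetic lineage and
    expression generators, and a benchmark harness for fraction-count and
    noise-robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
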