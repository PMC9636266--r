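Package: connsweep
Title: Threshold Sensitivity Analysis for EEG Functional Connectivity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how proportional thresholding shapes graph-theoretic
    analyses of electrophysiological functional connectivity. Estimates five
    spectral phase-synchronization measures (wPLI, imaginary coherency, coherence,
    ciPLV, pairwise phase consistency) from epoched multichannel recordings, sweeps
    quantile thresholds over connectivity matrices with isolated-node and
    largest-component pruning, computes global graph measures (median-hop
    characteristic path length, clustering coefficient, participation coefficient,
    small-world index), builds cohort-level edge-probability graphs, extracts
    orthogonal minimum spanning trees selected by global cost efficiency, and runs
    the statistical layer (metric-versus-density regression, cross-threshold
    Spearman structure, permutation t-tests with Cohen's d) on threshold sweeps.
    Includes a synthetic-cohort generator that plants known phase-lag coupling and
    group effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
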