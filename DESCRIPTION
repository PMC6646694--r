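Package: fcnbs
Title: Network-Based Statistics for Resting-State Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for group comparisons of resting-state
    functional connectomes. Converts ROI time series into Fisher-z
    connectivity matrices (nuisance regression, Chebyshev band-pass
    filtering, Pearson correlation), identifies altered edge components
    with network-based statistics (sign-test connection mask, edge-wise
    two-sample t tests, connected components of suprathreshold edges,
    permutation familywise-error control on maximal component size),
    classifies significant edges into change patterns, compares within-
    and between-network connectivity strengths with FDR control, and
    fits covariate-adjusted linear models linking edge strengths to
    clinical variables. Includes a synthetic-study generator with
    planted edge components for calibration and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
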