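Package: multimerK
Title: Finite-System Equilibrium Constants for Multimerization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cross-correlation-aware estimators of equilibrium constants for
    cluster formation in systems with small numbers of molecules. Implements
    falling-factorial (correlated) concentration moments, two-body and
    higher-order reaction-path expressions of K, transfer-reaction constants,
    probability-ratio forms, and fluctuation identities, together with an
    exact ideal-cluster ensemble oracle (partition-function enumeration), a
    Metropolis Monte Carlo sampler for Lennard-Jones particles in a periodic
    box with distance-criterion cluster detection, block-average error
    analysis, and scripted volume and system-size scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
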