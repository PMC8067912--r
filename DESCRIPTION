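Package: mrscan
Title: Fast Mutation-Response Scanning of Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mutation-response scanning of protein structures over
    anisotropic network models (ANM). Point mutations are modelled as
    random forces on the contacts of the mutated site; structural
    responses follow from the linear response approximation with the
    covariance matrix obtained as the pseudo-inverse of the ANM Hessian.
    The package computes the N x N sensitivity matrix S (mean squared
    structural response of each site to mutations at each site) and the
    compensation matrix D (maximal structural compensation achievable by
    a second mutation), each both by Monte-Carlo simulation and by exact
    closed-form expressions, together with normalisation, log-scale
    correlation and convergence diagnostics to compare the two routes.
    Includes a deterministic synthetic-fixture generator and brute-force
    oracles so every algorithmic claim is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
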