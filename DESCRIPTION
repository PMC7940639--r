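Package: riskclust
Title: Characterising, Identifying and Clustering Diseases by Risk-Factor
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterises diseases by the associations of their incidence
    with common risk factors, estimated from sex-specific proportional
    hazards models on the age timescale with left truncation and
    year-of-birth stratification.  Fitted maximum-likelihood estimates are
    treated as multivariate normals: marginalisation extracts a small set
    of biologically meaningful comparison parameters, multivariate
    chi-squared tests compare diseases between sexes, and the Bhattacharyya
    distance between parameter distributions drives opposite-sex disease
    identification and Ward.D2 hierarchical clustering with elbow-based
    cluster-count selection.  Includes a seeded synthetic multimorbidity
    cohort simulator with planted risk-profile clusters for validation, a
    statistical selection cascade (case floor, covariance eigenvalue
    screen, Bonferroni significance, FDR-adjusted proportional hazards
    test, unisex intersection), and clustering-stability metrics for
    sensitivity reanalyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
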