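Package: trackace
Title: Moderated Bivariate Cholesky ACE Models for Twin Data on Educational Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-environment-interaction analyses of twin data on
    educational performance and attainment. Implements the classical twin
    design (ACE variance decomposition), the bivariate Cholesky model in
    which attainment variance is split into parts common with and unique to
    performance, and continuous moderation of the attainment paths by the
    twin's own performance (definition variables). Models are estimated by
    full-information maximum likelihood over multiple zygosity-by-tracking
    groups, compared by likelihood-ratio tests, and summarised with
    decomposition tables, moderated variance curves, double-entry twin
    correlations, and Rao-Scott corrected crosstabs for clustered
    categorical data. A synthetic twin-pair generator with known parameters
    supports parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
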