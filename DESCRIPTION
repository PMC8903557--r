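Package: covertuse
Title: Covert Contraceptive Use from Discordant Couple Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study covert use of modern reversible contraceptive
    methods among matched wife-husband couples. Derives the covert-use
    outcome from discordant spousal reports, constructs normalized couple
    sampling weights from household weights and cluster-level couple
    response rates, measures the husband's egalitarian gender attitude with
    a binary latent class model fitted by expectation-maximization with
    AIC/BIC class selection, and estimates weighted bivariate and
    multivariate associations (Pearson chi-square cross-tabulations,
    logistic regression odds ratios with Wald intervals, McFadden
    pseudo-R-squared, variance inflation factors). Ships a synthetic
    couple-microdata generator with a three-class attitude structure and a
    cluster sampling design so the full pipeline is testable without survey
    microdata access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    yaml
Config/testthat/edition: 3
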