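Package: mippc
Title: Posterior Predictive Checking Diagnostics for Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for fully conditional specification (chained
    equations) multiple imputation models based on posterior predictive
    checking. Observed values of a target variable are over-imputed --
    duplicated, blanked, and multiply imputed -- so that each observed value
    can be compared with its own empirical posterior predictive distribution.
    Model fit is summarised by the coverage of nominal predictive intervals
    (COV), the mean absolute distance between observed values and replicate
    means (Distance), the mean interval width (CIW), and the mean squared
    deviance for binary targets, together with completed-data and
    expected-completed-data posterior predictive p-values. Includes a compact
    FCS imputation engine (Bayesian normal-linear, predictive mean matching,
    logistic, polynomial combination, and substantive-model-compatible
    quadratic methods), a weighted-sum-score amputation generator for MCAR
    and right-tailed MAR missingness, simulation-study scenario runners, and
    distribution, density, scatter, and deviance-residual plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
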