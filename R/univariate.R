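#' @useDynLib mippc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rchisq rnorm runif rbinom plogis qnorm quantile
#'   complete.cases glm.fit binomial coef lm density sd var uniroot qt pt
NULL

# Posterior draw for the normal-linear model under the standard
# noninformative prior p(beta, sigma^2) proportional to 1/sigma^2:
#   sigma*^2 = SSE / chisq_{n - q},  beta* | sigma* ~ N(beta_hat,
#   sigma*^2 (X'X)^-1).
# Returns beta_hat, beta_star, sigma_star.
norm_draw <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  q <- ncol(X)
  if (nrow(X) != n) stop("rows of the design must match length(y)")
  if (n <= q) {
    stop("need more observed cases (", n, ") than coefficients (", q, ")")
  }
  qx <- qr(X)
  if (qx$rank < q) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("col", seq_len(q))
    dropped <- cn[qx$pivot[(qx$rank + 1L):q]]
    stop("singular design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  beta_hat <- qr.coef(qx, y)
  sse <- sum(qr.resid(qx, y)^2)
  sigma2_star <- sse / rchisq(1L, n - q)
  # R such that R'R = X'X, aligned with the original column order
  R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  beta_star <- beta_hat + sqrt(sigma2_star) * backsolve(R, rnorm(q))
  list(beta_hat = beta_hat, beta_star = beta_star,
       sigma_star = sqrt(sigma2_star))
}

#' Bayesian normal-linear imputation draws
#'
#' Draws imputations for continuous targets from the posterior predictive
#' distribution of a normal-linear regression fitted to the observed cases:
#' parameters \eqn{(\beta^*, \sigma^*)} are drawn from the
#' noninformative-prior posterior and the returned values are
#' \eqn{X_{target}\beta^* + \sigma^* z}, \eqn{z \sim N(0,1)}.
#'
#' @param y_obs Observed outcome values.
#' @param X_obs Design matrix for observed rows (include an intercept column).
#' @param X_targets Design matrix for the rows to impute (same columns).
#' @return Numeric vector, one draw per row of `X_targets`.
#' @examples
#' set.seed(1)
#' impute_normal(rnorm(50), cbind(1, rnorm(50)), cbind(1, c(0, 1)))
#' @export
impute_normal <- function(y_obs, X_obs, X_targets) {
  X_targets <- as.matrix(X_targets)
  if (ncol(X_targets) != ncol(as.matrix(X_obs))) {
    stop("design matrices must share columns")
  }
  d <- norm_draw(y_obs, X_obs)
  drop(X_targets %*% d$beta_star) +
    d$sigma_star * rnorm(nrow(X_targets))
}

#' Predictive mean matching imputation draws
#'
#' Type-1 matching: predictions for observed rows use the least-squares
#' estimate \eqn{\hat\beta}, predictions for target rows use a posterior draw
#' \eqn{\beta^*}. For each target, the `donors` observed rows with the
#' smallest absolute distance between predictions form the donor pool, and
#' the imputed value is the observed outcome of one donor drawn uniformly.
#' Imputations therefore always fall within the observed sample space.
#'
#' @inheritParams impute_normal
#' @param donors Donor-pool size (default 5).
#' @return Numeric vector of borrowed observed values, one per target row.
#' @export
impute_pmm <- function(y_obs, X_obs, X_targets, donors = 5L) {
  if (donors < 1L) stop("`donors` must be >= 1")
  if (donors > length(y_obs)) {
    stop("`donors` (", donors, ") exceeds the number of observed cases (",
         length(y_obs), ")")
  }
  X_obs <- as.matrix(X_obs)
  X_targets <- as.matrix(X_targets)
  d <- norm_draw(y_obs, X_obs)
  yhat_obs <- drop(X_obs %*% d$beta_hat)
  yhat_t <- drop(X_targets %*% d$beta_star)
  idx <- .match_donors(yhat_obs, yhat_t, as.integer(donors))
  y_obs[idx]
}

#' Bayesian logistic imputation draws
#'
#' Fits a logistic regression to the observed binary outcomes by maximum
#' likelihood, draws \eqn{\beta^*} from the asymptotic normal approximation
#' \eqn{N(\hat\beta, \hat I^{-1})}, and imputes Bernoulli draws with
#' probabilities \eqn{\mathrm{logit}^{-1}(X_{target}\beta^*)}.
#'
#' @param y_obs Observed binary (0/1) outcome values.
#' @inheritParams impute_normal
#' @return Integer vector of 0/1 draws, one per target row.
#' @export
impute_logistic <- function(y_obs, X_obs, X_targets) {
  if (!all(y_obs %in% c(0, 1))) stop("y_obs must be binary (0/1)")
  X_obs <- as.matrix(X_obs)
  X_targets <- as.matrix(X_targets)
  if (all(y_obs == y_obs[1L])) {
    if (ncol(X_obs) > 1L) {
      stop("observed outcome is constant; the logistic model is not ",
           "identified (perfect separation)")
    }
    # intercept-only boundary: Jeffreys Beta(1/2, 1/2) posterior for the
    # success probability; draws converge to the constant as n_obs grows
    n1 <- sum(y_obs)
    p_star <- stats::rbeta(1L, 0.5 + n1, 0.5 + length(y_obs) - n1)
    return(rbinom(nrow(X_targets), 1L, p_star))
  }
  fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
  beta_hat <- fit$coefficients
  if (anyNA(beta_hat)) {
    stop("singular design: collinear column(s) ",
         paste(names(beta_hat)[is.na(beta_hat)], collapse = ", "))
  }
  if (!fit$converged || max(abs(beta_hat)) > 25 || fit$deviance < 1e-6) {
    stop("logistic fit did not converge; the observed classes appear ",
         "perfectly separated by the predictors")
  }
  q <- length(beta_hat)
  # glm.fit QR is of sqrt(W) X, so backsolve(R, z) ~ N(0, (X'WX)^-1)
  R <- qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE]
  beta_star <- beta_hat + backsolve(R, rnorm(q))
  p <- plogis(drop(X_targets %*% beta_star))
  rbinom(nrow(X_targets), 1L, p)
}
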