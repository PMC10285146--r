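# Imputation of a jointly missing (x, x^2) covariate pair under the
# quadratic substantive model  y = alpha + beta1 x + beta2 x^2 + eps.
# Both methods return pairs satisfying second = first^2 exactly, unlike
# chained PMM on x and x^2 as separate variables.

#' Polynomial combination imputation for a quadratic covariate pair
#'
#' Imputes a jointly missing \eqn{(X, X^2)} pair so that the square relation
#' holds exactly. The quadratic regression of `y` on \eqn{(x, x^2)} is fitted
#' to the observed rows; the linear combination
#' \eqn{c = \beta_1 x + \beta_2 x^2} is formed for observed rows and imputed
#' for missing rows by predictive mean matching on `y`; each imputed `c` is
#' then decomposed by solving \eqn{\beta_2 x^2 + \beta_1 x - c = 0}, choosing
#' the parabola arm stochastically from a logistic model of observed arm
#' membership on `y`.
#'
#' @param y_obs Outcome values for rows with `x` observed.
#' @param x_obs Observed covariate values.
#' @param y_mis Outcome values for rows whose \eqn{(x, x^2)} pair is missing.
#' @param donors PMM donor-pool size for the combination step.
#' @param max_redraw Cap on re-draws for (numerically) negative discriminants.
#' @return A matrix with columns `x` and `x2 = x^2`, one row per `y_mis`.
#' @export
impute_pc <- function(y_obs, x_obs, y_mis, donors = 5L, max_redraw = 100L) {
  qd <- norm_draw(y_obs, cbind(1, x_obs, x_obs^2))
  b <- qd$beta_hat  # (alpha, beta1, beta2)
  c_obs <- b[2L] * x_obs + b[3L] * x_obs^2

  # impute the combination by PMM of c on y (type-1 matching)
  c_imp <- impute_pmm(c_obs, cbind(1, y_obs), cbind(1, y_mis),
                      donors = donors)

  # arm membership model: which side of the vertex, as a function of y
  if (abs(b[3L]) < 1e-12) {
    x_new <- c_imp / b[2L]  # degenerate: single linear root
    return(cbind(x = x_new, x2 = x_new^2))
  }
  vertex <- -b[2L] / (2 * b[3L])
  arm <- as.integer(x_obs > vertex)
  p_pos <- if (length(unique(arm)) < 2L) {
    rep(mean(arm), length(y_mis))
  } else {
    af <- suppressWarnings(glm.fit(cbind(1, y_mis = y_obs), arm,
                                   family = binomial()))
    plogis(drop(cbind(1, y_mis) %*% af$coefficients))
  }

  disc <- b[2L]^2 + 4 * b[3L] * c_imp
  tries <- 0L
  while (any(neg <- disc < 0)) {
    # donor-borrowed c values keep the discriminant >= 0 up to rounding;
    # clamp tiny negatives, re-draw genuine ones
    tiny <- neg & disc > -1e-8 * max(1, b[2L]^2)
    disc[tiny] <- 0
    neg <- disc < 0
    if (!any(neg)) break
    tries <- tries + 1L
    if (tries > max_redraw) {
      stop("negative discriminant persisted after ", max_redraw,
           " re-draws for ", sum(neg), " row(s)")
    }
    c_imp[neg] <- impute_pmm(c_obs, cbind(1, y_obs),
                             cbind(1, y_mis[neg]), donors = donors)
    disc[neg] <- b[2L]^2 + 4 * b[3L] * c_imp[neg]
  }
  root <- sqrt(disc)
  pos <- runif(length(y_mis)) < p_pos
  x_new <- (-b[2L] + ifelse(pos, root, -root)) / (2 * b[3L])
  cbind(x = x_new, x2 = x_new^2)
}

#' Substantive-model-compatible imputation for a quadratic covariate pair
#'
#' Rejection sampler drawing the missing covariate from
#' \eqn{p(x \mid y) \propto \phi(x; \mu, \tau)\, f(y \mid x, \theta)} under
#' the quadratic substantive model. Substantive-model parameters
#' \eqn{\theta^* = (\alpha^*, \beta_1^*, \beta_2^*, \sigma^*)} and
#' normal covariate-model parameters \eqn{(\mu^*, \tau^*)} are drawn from
#' their noninformative-prior posteriors given the observed rows; proposals
#' \eqn{x^* \sim N(\mu^*, \tau^*)} are accepted with probability
#' \eqn{f(y \mid x^*, \theta^*) / c}, where `c` bounds the likelihood over a
#' 512-point grid spanning \eqn{\mu^* \pm 6\tau^*}.
#'
#' @inheritParams impute_pc
#' @param max_reject Proposal cap per missing row.
#' @param theta Optional fixed parameter list
#'   `list(alpha, beta1, beta2, sigma, mu, tau)` overriding the posterior
#'   draws (used for validation against a grid evaluation of `p(x | y)`).
#' @param grid_size Number of grid points for the rejection bound.
#' @return A matrix with columns `x` and `x2 = x^2`, one row per `y_mis`.
#' @export
impute_smcfcs_quadratic <- function(y_obs, x_obs, y_mis,
                                    max_reject = 100000L, theta = NULL,
                                    grid_size = 512L) {
  if (is.null(theta)) {
    qd <- norm_draw(y_obs, cbind(1, x_obs, x_obs^2))
    n <- length(x_obs)
    xbar <- mean(x_obs)
    tau2 <- sum((x_obs - xbar)^2) / rchisq(1L, n - 1L)
    theta <- list(alpha = qd$beta_star[1L], beta1 = qd$beta_star[2L],
                  beta2 = qd$beta_star[3L], sigma = qd$sigma_star,
                  mu = xbar + sqrt(tau2 / n) * rnorm(1L),
                  tau = sqrt(tau2))
  }
  nmis <- length(y_mis)
  grid <- seq(theta$mu - 6 * theta$tau, theta$mu + 6 * theta$tau,
              length.out = grid_size)
  mu_grid <- theta$alpha + theta$beta1 * grid + theta$beta2 * grid^2
  # per-row likelihood bound over the grid
  dens <- outer(y_mis, mu_grid, function(y, m) {
    stats::dnorm(y, m, theta$sigma)
  })
  cbound <- pmax(apply(dens, 1L, max), .Machine$double.xmin)

  # batched rejection sampling: the per-proposal acceptance probability can
  # be very small for rows with extreme y (the conditional mass sits far in
  # the proposal tails), so the per-row batch size grows geometrically; the
  # first accepted proposal in scan order is kept, which is exact rejection
  # sampling
  x_new <- rep(NA_real_, nmis)
  pending <- seq_len(nmis)
  used <- 0L
  batch <- 1L
  while (length(pending)) {
    if (used >= max_reject) {
      stop("rejection sampling exhausted ", max_reject,
           " proposals for row(s) ", paste(utils::head(pending, 5L),
                                           collapse = ", "))
    }
    batch <- min(2L * batch, 1024L, as.integer(max_reject - used))
    np <- length(pending)
    prop <- matrix(rnorm(np * batch, theta$mu, theta$tau), np, batch)
    lik <- stats::dnorm(y_mis[pending],
                        theta$alpha + theta$beta1 * prop +
                          theta$beta2 * prop^2,
                        theta$sigma)
    acc <- matrix(runif(np * batch), np, batch) < lik / cbound[pending]
    hit <- rowSums(acc) > 0L
    if (any(hit)) {
      first <- max.col(acc[hit, , drop = FALSE], ties.method = "first")
      x_new[pending[hit]] <- prop[cbind(which(hit), first)]
      pending <- pending[!hit]
    }
    used <- used + batch
  }
  cbind(x = x_new, x2 = x_new^2)
}
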