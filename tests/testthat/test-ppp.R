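# direct driver with fully controlled draws, for the boundary cases
stub_model <- function(y, mis, impute_val, rep_shift) {
  y_full <- y
  y_full[mis] <- impute_val
  structure(list(
    y = y, mis = mis,
    draw = function() list(),
    impute = function(theta) rep(impute_val, length(mis)),
    replicate = function(theta) y_full + rep_shift
  ), class = "ppc_model")
}

test_that("p-values hit the boundaries when one side always dominates", {
  y <- c(1, 2, NA, 4)
  up <- stub_model(y, 3, impute_val = 3, rep_shift = 10)
  expect_equal(ppp_completed(up, mean, n_draws = 25)$p_value, 1)
  down <- stub_model(y, 3, impute_val = 3, rep_shift = -10)
  r <- ppp_expected_completed(down, mean, n_outer = 10, n_inner = 4)
  expect_equal(r$p_value, 0)
  expect_true(all(r$differences < 0))
})

test_that("non-finite test quantities are reported with the draw index", {
  y <- c(1, 2, NA, 4)
  bad <- stub_model(y, 3, impute_val = 3, rep_shift = Inf)
  expect_error(ppp_completed(bad, mean, n_draws = 3), "draw 1")
})

test_that("an inner count of one reduces to single-draw differences", {
  set.seed(21)
  d <- gen_quadratic_outcome(80)
  y <- d$y; y[1:20] <- NA
  model <- ppc_norm_model(y, cbind(1, d$x, d$x2))
  r <- ppp_expected_completed(model, mean, n_outer = 15, n_inner = 1)
  expect_equal(dim(r$differences), c(15, 1))
  expect_equal(r$d_bar, drop(r$differences))
  expect_equal(r$p_value, mean(r$d_bar >= 0))
})

test_that("inner averaging reduces the variance of the discrepancy", {
  set.seed(22)
  d <- gen_quadratic_outcome(150)
  y <- d$y; y[1:60] <- NA
  model <- ppc_norm_model(y, cbind(1, d$x, d$x2))
  r <- ppp_expected_completed(model, mean, n_outer = 150, n_inner = 15)
  expect_lt(var(r$d_bar), var(r$differences[, 1]))
})

test_that("a congenial model keeps completed-data p-values away from the extremes", {
  # normal-mean model with a flat prior, T = sample mean: the
  # completed-data posterior predictive p-value is (up to simulation
  # noise) exactly 1/2 for every dataset, the classical conservatism of
  # posterior predictive checks -- so across regenerated datasets the
  # p-values must concentrate near 0.5 and never approach 0 or 1
  set.seed(23)
  ps <- replicate(200, {
    y <- rnorm(60, mean = 2)
    y[1:15] <- NA
    m <- ppc_norm_model(y, matrix(1, 60, 1))
    ppp_completed(m, mean, n_draws = 60)$p_value
  })
  expect_gt(min(ps), 0.05)
  expect_lt(max(ps), 0.95)
  expect_lt(abs(mean(ps) - 0.5), 0.03)
})

test_that("residual skewness exposes the misspecified linear imputation model", {
  set.seed(24)
  d <- gen_quadratic_outcome(500)
  inc <- ampute(d, amputation_spec("y", 0.3, "MCAR", seed = 25))
  y <- ifelse(inc$observed[, "y"], inc$values[, "y"], NA)
  X_lin <- cbind(1, d$x)  # imputation model omits the quadratic term
  model <- ppc_norm_model(y, X_lin)
  skew_resid <- function(yy) {
    r <- stats::lm.fit(X_lin, yy)$residuals
    mean((r - mean(r))^3) / sd(r)^3
  }
  p <- ppp_completed(model, skew_resid, n_draws = 150)$p_value
  expect_true(p < 0.05 || p > 0.95)
})
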