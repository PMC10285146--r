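test_that("normal-linear draws degenerate to the constant when residual variance is zero", {
  set.seed(1)
  draws <- impute_normal(rep(4, 12), matrix(1, 12, 1), matrix(1, 5, 1))
  expect_equal(draws, rep(4, 5))
})

test_that("normal-linear predictive draws center on the least-squares prediction", {
  set.seed(42)
  n <- 5000
  x <- runif(n, -2, 2)
  y <- 1 + 2 * x + rnorm(n)
  X <- cbind(1, x)
  x0 <- c(1, 0.7)
  pred <- sum(stats::lm.fit(X, y)$coefficients * x0)
  B <- 400
  draws <- replicate(B, impute_normal(y, X, rbind(x0)))
  mc_se <- sd(draws) / sqrt(B)
  expect_lt(abs(mean(draws) - pred), 3 * mc_se)
})

test_that("posterior coefficient draws reproduce the closed-form covariance", {
  set.seed(7)
  n <- 400
  x <- runif(n, 0, 3)  # nonzero mean keeps every covariance entry away from 0
  X <- cbind(1, x)
  y <- drop(X %*% c(0.5, 1)) + rnorm(n)
  qx <- qr(X)
  s2 <- sum(qr.resid(qx, y)^2) / (n - 2)
  target <- s2 * chol2inv(qr.R(qx))
  B <- 10000
  bs <- t(replicate(B, mippc:::norm_draw(y, X)$beta_star))
  emp <- cov(bs)
  expect_true(all(abs(emp - target) <= 0.05 * abs(target)))
})

test_that("singular and underdetermined designs are rejected with named columns", {
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(impute_normal(rnorm(10), X, X[1:2, ]), "collinear.*c")
  expect_error(impute_normal(rnorm(2), cbind(1, 1:2), cbind(1, 1)),
               "more observed cases")
})

test_that("PMM borrows only observed values and picks the nearest donor", {
  set.seed(3)
  n <- 200
  x <- rnorm(n)
  y <- x + rnorm(n)
  X <- cbind(1, x)
  imp <- impute_pmm(y, X, cbind(1, rnorm(50)), donors = 5)
  expect_true(all(imp %in% y))

  # perfectly linear fit (zero residual variance) makes matching exact:
  # target prediction 2.2 with a single donor must borrow y = 2
  y5 <- c(1, 2, 3, 4, 5)
  X5 <- cbind(1, y5)  # y = 0 + 1*x exactly
  set.seed(11)
  expect_equal(impute_pmm(y5, X5, rbind(c(1, 2.2)), donors = 1), 2)
  expect_error(impute_pmm(y5, X5, rbind(c(1, 2.2)), donors = 6),
               "exceeds the number of observed cases")
})

test_that("logistic imputation recovers the correct success probability", {
  set.seed(9)
  n <- 20000
  x <- runif(n, -3, 3)
  z <- rnorm(n, 1, 1)
  y <- rbinom(n, 1, plogis(x + z))
  X <- cbind(1, x, z)
  # at (x, z) = (0, 0) the true success probability is logistic(0) = 0.5
  B <- 5000
  tgt <- matrix(rep(c(1, 0, 0), each = B), nrow = B)
  frac <- mean(impute_logistic(y, X, tgt))
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("constant binary outcomes give near-degenerate draws, separation errors", {
  set.seed(5)
  draws <- impute_logistic(rep(1, 5000), matrix(1, 5000, 1),
                           matrix(1, 500, 1))
  expect_gt(mean(draws), 0.99)

  # a predictor that perfectly separates the classes must be diagnosed
  xs <- c(-3, -2, -1, 1, 2, 3)
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_error(impute_logistic(ys, cbind(1, xs), cbind(1, 0)), "separat")
})
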