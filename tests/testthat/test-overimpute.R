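test_that("the duplicate-and-blank design has the advertised shape", {
  d <- gen_quadratic_outcome(10, seed = 1)
  d$y[1:3] <- NA
  des <- build_overimputation_design(d, "y")
  expect_equal(nrow(des$design$values), 14)  # 7 observed rows + 7 duplicates
  expect_equal(sum(des$where), 7)
  expect_true(all(is.na(des$design$values[des$where])))
  # duplicates carry their source covariates
  expect_equal(des$design$values[des$row_map$duplicate, "x"],
               des$design$values[des$row_map$source, "x"])

  # fully observed input: 2n rows, n marked cells
  full <- gen_quadratic_outcome(25, seed = 2)
  des2 <- build_overimputation_design(full, "y")
  expect_equal(nrow(des2$design$values), 50)
  expect_equal(sum(des2$where), n_observed(full, "y"))

  allmis <- data.frame(x = 1:4, y = rep(NA_real_, 4))
  expect_error(build_overimputation_design(allmis, "y"), "never observed")
})

test_that("replicate summaries collapse correctly when draws equal the data", {
  obs <- c(-1, 0, 2.5)
  rep <- make_rep(obs, matrix(rep(obs, 10), nrow = 3))
  s <- summarize_replicates(rep, 0.95)
  expect_equal(s$cov, 1)
  expect_equal(s$distance, 0)
  expect_equal(s$ciw, 0)
  expect_error(summarize_replicates(make_rep(0, matrix(c(1, NA), 1)), 0.95),
               "finite")
  expect_error(summarize_replicates(rep, 1.2), "in \\(0, 1\\)")
})

test_that("interval bounds agree with a brute-force sort-and-interpolate oracle", {
  set.seed(12)
  for (m in c(7, 50, 201)) {
    draws <- matrix(rnorm(40 * m, sd = runif(1, 0.5, 3)), nrow = 40)
    rep <- make_rep(rnorm(40), draws)
    for (level in c(0.75, 0.95)) {
      s <- summarize_replicates(rep, level)
      a <- (1 - level) / 2
      lo <- apply(draws, 1, oracle_quantile5, p = a)
      hi <- apply(draws, 1, oracle_quantile5, p = 1 - a)
      expect_equal(s$lower, lo, tolerance = 1e-12)
      expect_equal(s$upper, hi, tolerance = 1e-12)
      expect_equal(s$center, rowMeans(draws))
      expect_equal(s$cov, mean(rep$obs >= lo & rep$obs <= hi))
    }
  }
})

test_that("large-m intervals reach the analytic normal limits", {
  # a correct normal model with sigma = 1: CIW -> 2 * z_{1-alpha/2}
  # (3.92 at 95%, 2.30 at 75%) and Distance -> sqrt(2/pi) = 0.798
  # ciw averages the per-point widths, so a block of iid rows tightens the
  # Monte-Carlo error without changing what is measured per point
  set.seed(13)
  one <- make_rep(rep(0, 50), matrix(rnorm(50 * 10000), nrow = 50))
  s95 <- summarize_replicates(one, 0.95)
  s75 <- summarize_replicates(one, 0.75)
  expect_lt(abs(s95$ciw - 2 * qnorm(0.975)) / (2 * qnorm(0.975)), 0.02)
  expect_lt(abs(s75$ciw - 2 * qnorm(0.875)) / (2 * qnorm(0.875)), 0.02)

  n <- 10000; m <- 100
  many <- make_rep(rnorm(n), matrix(rnorm(n * m), nrow = n))
  d <- summarize_replicates(many, 0.95)$distance
  expect_lt(abs(d - sqrt(2 / pi)) / sqrt(2 / pi), 0.02)
})

test_that("mean squared deviance follows the clipped analytic values", {
  # y = 1 against replicate probability 0.5: contribution 2 log 2
  rep1 <- make_rep(1, matrix(rep(0:1, 25), nrow = 1), kind = "binary")
  expect_equal(mean_squared_deviance(rep1), 2 * log(2))
  # y = 1 with all m = 50 draws equal 1: clipping at 1 - 1/(2m) gives
  # -2 log(1 - 1/100)
  rep2 <- make_rep(1, matrix(1, 1, 50), kind = "binary")
  expect_equal(mean_squared_deviance(rep2), -2 * log(1 - 1 / 100))
  expect_equal(abs(deviance_residuals(rep2)),
               sqrt(-2 * log(1 - 1 / 100)))
  expect_error(mean_squared_deviance(make_rep(0.5, matrix(1, 1, 4))),
               "binary")
})

test_that("overimpute_check wires design, imputation, and summaries together", {
  d <- gen_quadratic_outcome(150, seed = 14)
  inc <- ampute(d, amputation_spec("y", 0.3, "MCAR", seed = 15))
  chk <- overimpute_check(inc, "y", m = 15, levels = c(0.75, 0.95),
                          seed = 16)
  n_obs <- n_observed(inc, "y")
  expect_equal(length(chk$rep$obs), n_obs)
  expect_equal(dim(chk$rep$draws), c(n_obs, 15))
  expect_equal(chk$summaries$level_0.95$level, 0.95)
  expect_null(chk$deviance)
  # deterministic given the seed
  chk2 <- overimpute_check(inc, "y", m = 15, levels = c(0.75, 0.95),
                           seed = 16)
  expect_identical(chk$rep$draws, chk2$rep$draws)
})
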