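make_check <- function(model = "quadratic", seed = 41) {
  d <- gen_quadratic_outcome(400, seed = seed)
  inc <- ampute(d, amputation_spec("y", 0.3, "MARr", weights = c(x = 1),
                                   seed = seed + 1))
  vars <- c("x", "x2", "y")
  pred <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  pred["y", if (model == "quadratic") c("x", "x2") else "x"] <- TRUE
  spec <- method_spec(c(x = "none", x2 = "none", y = "norm"), pred)
  overimpute_check(inc, "y", spec = spec, m = 25, levels = 0.95,
                   seed = seed + 2)
}

test_that("distribution-plot data flags exactly the non-covered points", {
  chk <- make_check()
  s <- chk$summaries[[1]]
  d <- distribution_plot_data(s)
  expect_equal(sum(!d$covered), round(length(s$obs) * (1 - s$cov)))
  expect_false(is.unsorted(d$center))
  # an all-covered summary flags nothing
  all_in <- make_rep(0, matrix(rnorm(200), nrow = 1))
  s2 <- summarize_replicates(all_in, 0.95)
  expect_equal(sum(!distribution_plot_data(s2)$covered), 0)
  p <- distribution_plot(s)
  expect_s3_class(p, "ggplot")
})

test_that("misfit concentrates interval misses at the tails", {
  quad <- distribution_plot_data(make_check("quadratic")$summaries[[1]])
  lin <- distribution_plot_data(make_check("linear")$summaries[[1]])
  # distance of flagged points from the middle rank, misfit vs fit:
  # the linear model must flag points systematically further out
  tail_dist <- function(d) abs(d$rank[!d$covered] - (nrow(d) + 1) / 2)
  expect_gt(length(tail_dist(lin)), 0)
  w <- stats::wilcox.test(tail_dist(lin), tail_dist(quad),
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("replicate distributions track the observed data only under the fit model", {
  quad <- make_check("quadratic")
  lin <- make_check("linear")
  ks_stat <- function(chk) {
    suppressWarnings(stats::ks.test(chk$rep$obs,
                                    as.vector(chk$rep$draws))$statistic)
  }
  expect_lt(ks_stat(quad), 0.05)
  expect_gt(ks_stat(lin), 2 * ks_stat(quad))
})

test_that("comparison plot data and files are produced", {
  chk <- make_check()
  x <- chk$design$design$values[chk$design$row_map$source, "x"]
  d <- comparison_plot_data(chk$rep, covariate = x, m_show = 4)
  n_obs <- length(chk$rep$obs)
  expect_equal(nrow(d), n_obs * 5)  # observed block + 4 replicate blocks
  expect_equal(sum(d$role == "observed"), n_obs)
  # identical replicates give coinciding densities on a shared grid
  same <- make_rep(chk$rep$obs,
                   matrix(rep(chk$rep$obs, 3), ncol = 3))
  grid <- seq(min(chk$rep$obs), max(chk$rep$obs), length.out = 101)
  d_obs <- stats::density(same$obs, from = grid[1], to = grid[101], n = 101)
  d_rep <- stats::density(same$draws[, 1], from = grid[1], to = grid[101],
                          n = 101)
  expect_lt(max(abs(d_obs$y - d_rep$y)), 1e-9)

  tmp <- withr::local_tempdir()
  out <- comparison_plots(chk$rep, covariate = x, m_show = 3,
                          file = file.path(tmp, "cmp"))
  expect_true(all(file.exists(out$files)))
  expect_true(all(file.size(out$files) > 0))
})

test_that("deviance residuals shrink when the imputation model fits", {
  d <- gen_logistic(500, seed = 51)
  inc <- ampute(d, amputation_spec("y", 0.3, "MCAR", seed = 52))
  vars <- c("y", "x", "z")
  spec_for <- function(preds) {
    pred <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
    pred["y", preds] <- TRUE
    method_spec(c(y = "logreg", x = "none", z = "none"), pred)
  }
  with_x <- overimpute_check(inc, "y", spec_for(c("x", "z")), m = 30,
                             seed = 53)
  z_only <- overimpute_check(inc, "y", spec_for("z"), m = 30, seed = 53)
  r_fit <- deviance_residuals(with_x$rep)
  r_mis <- deviance_residuals(z_only$rep)
  expect_lt(mean(r_fit^2), mean(r_mis^2))

  # near-perfect replicate probabilities leave residuals within the
  # clipping bound sqrt(2/(2m)) * c
  m <- 30
  perfect <- make_rep(c(0, 1), matrix(rep(c(0, 1), m), nrow = 2),
                      kind = "binary")
  expect_true(all(abs(deviance_residuals(perfect)) <=
                    sqrt(-2 * log(1 - 1 / (2 * m))) + 1e-12))

  p <- deviance_plot(with_x$rep)
  expect_s3_class(p, "ggplot")
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "dev.png")
  deviance_plot(with_x$rep, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
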