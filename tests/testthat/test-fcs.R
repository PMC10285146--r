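test_that("fully observed data with an empty mask passes through unchanged", {
  d <- gen_quadratic_outcome(30, seed = 1)
  imp <- fcs_impute(d, m = 3, seed = 2)
  for (i in 1:3) expect_equal(imp$completed[[i]], as_incomplete_data(d)$values)
})

test_that("a fixed seed reproduces the imputations bit for bit", {
  d <- toy_incomplete()
  spec <- method_spec(c(x = "none", y = "norm"))
  a <- fcs_impute(d, spec, m = 4, seed = 99)
  b <- fcs_impute(d, spec, m = 4, seed = 99)
  expect_identical(a$completed, b$completed)
  # early streams are unchanged when m grows
  c6 <- fcs_impute(d, spec, m = 6, seed = 99)
  expect_identical(a$completed, c6$completed[1:4])
})

test_that("extra sweeps do not alter single-variable imputation", {
  d <- toy_incomplete()
  spec <- method_spec(c(x = "none", y = "norm"))
  a <- fcs_impute(d, spec, m = 3, n_iter = 1, seed = 5)
  b <- fcs_impute(d, spec, m = 3, n_iter = 10, seed = 5)
  expect_identical(a$completed, b$completed)
})

test_that("over-imputation rows never contribute to model fitting", {
  # base rows follow y = 2x exactly; if the duplicated rows (initially
  # filled with random draws) leaked into the fit, the residual variance
  # would be positive and the imputed values could not reproduce 2x exactly
  x <- seq(-3, 3, length.out = 20)
  d <- data.frame(x = x, y = 2 * x)
  des <- build_overimputation_design(incomplete_data(d), "y")
  pred <- matrix(FALSE, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  pred["y", "x"] <- TRUE
  spec <- method_spec(c(x = "none", y = "norm"), predictors = pred)
  imp <- fcs_impute(des$design, spec, where = des$where, m = 2, seed = 3)
  for (i in 1:2) {
    got <- imp$completed[[i]][des$row_map$duplicate, "y"]
    expect_equal(got, 2 * x, tolerance = 1e-10)
  }
})

test_that("unmarked cells are identical across imputations and marked cells vary", {
  d <- gen_quadratic_outcome(120, seed = 4)
  d$y[1:40] <- NA
  spec <- method_spec(c(x = "none", x2 = "none", y = "norm"),
                      predictors = matrix(c(rep(FALSE, 6), TRUE, TRUE, FALSE),
                                          3, 3, byrow = TRUE,
                                          dimnames = list(c("x", "x2", "y"),
                                                          c("x", "x2", "y"))))
  imp <- fcs_impute(d, spec, m = 8, seed = 6)
  base <- as_incomplete_data(d)
  for (i in 1:8) {
    expect_identical(imp$completed[[i]][!imp$where], base$values[!imp$where])
    expect_false(anyNA(imp$completed[[i]]))
  }
  # proper imputation: positive across-stream variance at imputed cells
  cell_draws <- sapply(imp$completed, function(w) w[1, "y"])
  expect_gt(var(cell_draws), 0)
})

test_that("method/mask inconsistencies and unreachable predictors are caught", {
  d <- toy_incomplete()
  expect_error(fcs_impute(d, method_spec(c(x = "none", y = "none"))),
               'method "none"')
  expect_error(fcs_impute(d, method_spec(c(x = "norm", y = "norm"))),
               'must use\\s+method "none"')
  expect_error(fcs_impute(d, method_spec(c(x = "none", y = "norm")), m = 0),
               "`m` must be >= 1")
  # a target whose only rows are all marked has nothing to fit on
  allmis <- incomplete_data(data.frame(x = 1:5, y = rep(NA_real_, 5)))
  expect_error(fcs_impute(allmis, method_spec(c(x = "none", y = "norm"))),
               "no genuinely observed cases")
})
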