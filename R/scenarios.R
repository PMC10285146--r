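# Synthetic data generators and study runners for the three simulation
# designs used to calibrate and stress the diagnostic. All three fix the
# substantive parameters alpha = 0, beta1 = 1, beta2 = 1 and unit residual
# SD, with n = 1000 cases and m = 50 imputations by default.

#' Quadratic model with an incomplete outcome (study 1 design)
#'
#' \eqn{X \sim U(-3, 3)}, \eqn{Y = X + X^2 + \epsilon},
#' \eqn{\epsilon \sim N(0, 1)}. The returned frame also carries the exact
#' square `x2` so imputation models may include or omit the quadratic term.
#'
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return A data frame with columns `x`, `x2`, `y`.
#' @export
gen_quadratic_outcome <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, -3, 3)
  y <- x + x^2 + rnorm(n)
  data.frame(x = x, x2 = x^2, y = y)
}

#' Quadratic model with an incomplete covariate pair (study 2 design)
#'
#' \eqn{X \sim N(0, 1)}, `x2` the exact square,
#' \eqn{Y = X + X^2 + \epsilon}, \eqn{\epsilon \sim N(0, 1)}. In the study,
#' `x` and `x2` are amputed jointly while `y` stays complete.
#'
#' @inheritParams gen_quadratic_outcome
#' @return A data frame with columns `y`, `x`, `x2`.
#' @export
gen_quadratic_covariate <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  y <- x + x^2 + rnorm(n)
  data.frame(y = y, x = x, x2 = x^2)
}

#' Logistic model with an incomplete binary outcome (study 3 design)
#'
#' \eqn{X \sim U(-3, 3)}, \eqn{Z \sim N(1, 1)},
#' \eqn{\Pr(Y = 1 \mid X, Z) = \mathrm{logit}^{-1}(X + Z)}.
#'
#' @inheritParams gen_quadratic_outcome
#' @return A data frame with columns `y` (0/1), `x`, `z`.
#' @export
gen_logistic <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, -3, 3)
  z <- rnorm(n, 1, 1)
  y <- rbinom(n, 1L, plogis(x + z))
  data.frame(y = y, x = x, z = z)
}

#' Scenario configuration for a simulation-study cell
#'
#' @param study `"quad_outcome"`, `"quad_covariate"`, or `"logistic"`.
#' @param n Sample size (default 1000).
#' @param m Imputations per model (default 50).
#' @param prop Missingness proportion (0.30, 0.50, or 0.80 in the studies).
#' @param mechanism `"MCAR"` or `"MARr"`.
#' @param levels Nominal interval levels (default 0.75 and 0.95).
#' @param models Candidate imputation models to compare; defaults per study
#'   (`linear`/`quadratic`, `pmm`/`pc`/`smcfcs`, `with_x`/`z_only`).
#' @param seed Integer master seed for the cell.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(study = c("quad_outcome", "quad_covariate",
                                      "logistic"),
                            n = 1000L, m = 50L, prop = 0.30,
                            mechanism = c("MCAR", "MARr"),
                            levels = c(0.75, 0.95), models = NULL,
                            seed = 1L) {
  study <- match.arg(study)
  mechanism <- match.arg(mechanism)
  stopifnot(n >= 10L, prop > 0, prop < 1)
  if (is.null(models)) {
    models <- switch(study,
                     quad_outcome = c("linear", "quadratic"),
                     quad_covariate = c("pmm", "pc", "smcfcs"),
                     logistic = c("with_x", "z_only"))
  }
  structure(list(study = study, n = as.integer(n), m = as.integer(m),
                 prop = prop, mechanism = mechanism, levels = levels,
                 models = models, seed = as.integer(seed)),
            class = "scenario_config")
}

# method spec for one named candidate model on an over-imputation design
scenario_method_spec <- function(study, model, design, donors = 5L) {
  vars <- design$design$var_names
  none <- stats::setNames(rep("none", length(vars)), vars)
  pred <- matrix(FALSE, length(vars), length(vars),
                 dimnames = list(vars, vars))
  if (study == "quad_outcome") {
    methods <- none; methods["y"] <- "norm"
    pred["y", if (model == "linear") "x" else c("x", "x2")] <- TRUE
    method_spec(methods, pred)
  } else if (study == "quad_covariate") {
    methods <- none
    if (model == "pmm") {
      methods[c("x", "x2")] <- "pmm"
      pred["x", c("y", "x2")] <- TRUE
      pred["x2", c("y", "x")] <- TRUE
      method_spec(methods, pred, donors = donors)
    } else {
      methods[c("x", "x2")] <- if (model == "pc") "pc" else "smcfcs"
      method_spec(methods, pred, donors = donors,
                  quadratic = list(x = "x", x2 = "x2", y = "y"))
    }
  } else {
    methods <- none; methods["y"] <- "logreg"
    pred["y", if (model == "with_x") c("x", "z") else "z"] <- TRUE
    method_spec(methods, pred)
  }
}

scenario_amputation <- function(study, prop, mechanism, seed) {
  switch(study,
         quad_outcome = amputation_spec(
           "y", prop, mechanism,
           weights = if (mechanism == "MARr") c(x = 1), seed = seed),
         quad_covariate = amputation_spec(
           c("x", "x2"), prop, mechanism,
           weights = if (mechanism == "MARr") c(y = 1), seed = seed),
         logistic = amputation_spec(
           "y", prop, mechanism,
           weights = if (mechanism == "MARr") c(x = 1, z = 1), seed = seed))
}

#' Run one simulation-study cell
#'
#' Generates one complete dataset, amputes it per the configuration, builds
#' the over-imputation design for the study's target, imputes it with each
#' candidate model, and reports one row per (model, level) with COV,
#' Distance, and CIW — or one row per model with the mean squared deviance
#' for the binary study. Deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `study`, `prop`, `mechanism`, `model`,
#'   `level`, `cov`, `distance`, `ciw`, `deviance`.
#' @examples
#' run_study(scenario_config("quad_outcome", n = 200, m = 10, seed = 1))
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max,
                    2L + length(config$models))
  gen <- switch(config$study,
                quad_outcome = gen_quadratic_outcome,
                quad_covariate = gen_quadratic_covariate,
                logistic = gen_logistic)
  dat <- gen(config$n, seed = sub[1L])
  amp <- scenario_amputation(config$study, config$prop, config$mechanism,
                             seed = sub[2L])
  inc <- ampute(dat, amp)
  target <- if (config$study == "quad_covariate") c("x", "x2") else "y"

  rows <- list()
  for (i in seq_along(config$models)) {
    model <- config$models[i]
    design <- build_overimputation_design(inc, target)
    spec <- scenario_method_spec(config$study, model, design)
    chk <- overimpute_check(inc, target, spec = spec, m = config$m,
                            levels = config$levels, seed = sub[2L + i])
    if (config$study == "logistic") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        study = config$study, prop = config$prop,
        mechanism = config$mechanism, model = model, level = NA_real_,
        cov = NA_real_, distance = NA_real_, ciw = NA_real_,
        deviance = chk$deviance)
    } else {
      for (s in chk$summaries) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          study = config$study, prop = config$prop,
          mechanism = config$mechanism, model = model, level = s$level,
          cov = s$cov, distance = s$distance, ciw = s$ciw,
          deviance = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full factorial grid of a study
#'
#' Covers missingness proportions x mechanisms for one study, one
#' independently seeded cell each, mirroring the layout of the study tables.
#'
#' @inheritParams scenario_config
#' @param props Missingness proportions to cover.
#' @param mechanisms Mechanisms to cover.
#' @param seed Master seed; cell seeds are derived from it.
#' @return A tibble of stacked [run_study()] results.
#' @export
run_factorial <- function(study, props = c(0.30, 0.50, 0.80),
                          mechanisms = c("MCAR", "MARr"), n = 1000L,
                          m = 50L, levels = c(0.75, 0.95), seed = 1L) {
  grid <- expand.grid(prop = props, mechanism = mechanisms,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    run_study(scenario_config(study, n = n, m = m, prop = grid$prop[i],
                              mechanism = grid$mechanism[i],
                              levels = levels, seed = cell_seeds[i]))
  })
  do.call(rbind, out)
}

# Rubin's rules for one coefficient across m completed-data fits,
# with Barnard-Rubin small-sample degrees of freedom.
pool_rubin <- function(est, se2, df_com) {
  m <- length(est)
  qbar <- mean(est)
  ubar <- mean(se2)
  b <- var(est)
  t_var <- ubar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / t_var
  df_old <- (m - 1) / lambda^2
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df <- df_old * df_obs / (df_old + df_obs)
  list(estimate = qbar, se = sqrt(t_var), df = df)
}

#' Parameter recovery of the quadratic fit under chained PMM imputation
#'
#' Repeated-dataset check of downstream inference: in each repetition a
#' complete study-2 dataset is generated, the \eqn{(x, x^2)} pair is amputed
#' jointly under MCAR, the genuinely missing cells are multiply imputed by
#' chained predictive mean matching, the quadratic regression
#' \eqn{Y = \alpha + \beta_1 X + \beta_2 X^2 + \epsilon} is fitted to every
#' completed dataset, and the fits are pooled by Rubin's rules. Reports the
#' mean pooled estimates of \eqn{\beta_1, \beta_2} (truth: 1 and 1) and the
#' empirical coverage of their nominal 95% confidence intervals.
#'
#' @param n_reps Number of repetitions (independent datasets).
#' @param n Sample size per dataset.
#' @param prop MCAR missingness proportion.
#' @param m Imputations per dataset.
#' @param donors PMM donor-pool size.
#' @param seed Integer master seed.
#' @return A tibble with one row per coefficient: `term`, `true`,
#'   `estimate` (mean pooled estimate), `coverage` (95% CI), `n_reps`.
#' @export
run_parameter_recovery <- function(n_reps = 200L, n = 1000L, prop = 0.30,
                                   m = 50L, donors = 5L, seed = 1L) {
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_reps),
                      nrow = n_reps)
  est <- cov_hit <- matrix(NA_real_, n_reps, 2L)
  truth <- c(1, 1)
  for (r in seq_len(n_reps)) {
    dat <- gen_quadratic_covariate(n, seed = rep_seeds[r, 1L])
    inc <- ampute(dat, amputation_spec(c("x", "x2"), prop, "MCAR",
                                       seed = rep_seeds[r, 2L]))
    vars <- inc$var_names
    methods <- stats::setNames(c("none", "pmm", "pmm"), vars)
    pred <- matrix(FALSE, 3L, 3L, dimnames = list(vars, vars))
    pred["x", c("y", "x2")] <- TRUE
    pred["x2", c("y", "x")] <- TRUE
    spec <- method_spec(methods, pred, donors = donors)
    imp <- fcs_impute(inc, spec, m = m, seed = rep_seeds[r, 3L])
    coefs <- ses2 <- matrix(NA_real_, m, 2L)
    for (i in seq_len(m)) {
      w <- imp$completed[[i]]
      fit <- stats::lm.fit(cbind(1, w[, "x"], w[, "x2"]), w[, "y"])
      rss <- sum(fit$residuals^2)
      s2 <- rss / fit$df.residual
      R <- qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE]
      vc <- chol2inv(R) * s2
      coefs[i, ] <- fit$coefficients[2:3]
      ses2[i, ] <- diag(vc)[2:3]
    }
    for (k in 1:2) {
      pl <- pool_rubin(coefs[, k], ses2[, k], df_com = n - 3L)
      est[r, k] <- pl$estimate
      half <- qt(0.975, pl$df) * pl$se
      cov_hit[r, k] <- abs(pl$estimate - truth[k]) <= half
    }
  }
  tibble::tibble(term = c("beta1", "beta2"), true = truth,
                 estimate = colMeans(est), coverage = colMeans(cov_hit),
                 n_reps = n_reps)
}
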