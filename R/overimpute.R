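#' Build the duplicate-and-over-impute design for a target variable
#'
#' The over-imputation design behind the diagnostic: (1) remove the rows
#' incomplete on the target, (2) duplicate the remaining rows, (3) blank the
#' target in the duplicates, and (4) mark exactly the blanked cells for
#' imputation. Imputing the design then yields, for every observed target
#' value, draws from its posterior predictive distribution, while the
#' duplicated rows never contribute to model fitting.
#'
#' @param data An `incomplete_data` object (or coercible).
#' @param target Variable name whose observed values are checked. May be a
#'   character vector of columns blanked jointly (e.g. a covariate and its
#'   exact square); the first element is the primary variable summarised.
#' @return An object of class `overimpute_design`: list with `design` (the
#'   augmented `incomplete_data`), `where` (logical mask marking the blanked
#'   cells), `row_map` (data frame linking each duplicate row to its source
#'   row), and `target`.
#' @examples
#' d <- gen_quadratic_outcome(10, seed = 1)
#' d$y[1:3] <- NA
#' des <- build_overimputation_design(d, "y")
#' nrow(des$design$values)  # 14: 7 observed rows + 7 duplicates
#' sum(des$where)           # 7 blanked cells
#' @export
build_overimputation_design <- function(data, target) {
  data <- as_incomplete_data(data)
  if (!all(target %in% data$var_names)) {
    stop("target variable(s) not found: ",
         paste(setdiff(target, data$var_names), collapse = ", "))
  }
  keep <- rowSums(!data$observed[, target, drop = FALSE]) == 0L
  nk <- sum(keep)
  if (nk == 0L) stop("target '", target[1L], "' is never observed")
  if (nk < 2L) stop("need at least 2 rows observed on the target")

  base_v <- data$values[keep, , drop = FALSE]
  dup_v <- base_v
  dup_v[, target] <- NA_real_
  values <- rbind(base_v, dup_v)
  rownames(values) <- NULL
  design <- incomplete_data(values, var_kinds = data$var_kinds)

  where <- matrix(FALSE, nrow(values), ncol(values),
                  dimnames = list(NULL, colnames(values)))
  where[nk + seq_len(nk), target] <- TRUE

  structure(
    list(design = design, where = where,
         row_map = data.frame(source = seq_len(nk),
                              duplicate = nk + seq_len(nk)),
         target = target),
    class = "overimpute_design"
  )
}

#' Replicate matrix for a checked variable
#'
#' Pairs each observed value of the target with its `m` over-imputed
#' replicate draws.
#'
#' @param imp A `mimp` object from imputing an over-imputation design.
#' @param design The `overimpute_design` the imputation was run on.
#' @return An object of class `replicate_matrix`: list with `obs` (length
#'   n_obs), `draws` (n_obs x m matrix), `kind`, and `target`.
#' @export
replicate_matrix <- function(imp, design) {
  stopifnot(inherits(imp, "mimp"), inherits(design, "overimpute_design"))
  primary <- design$target[1L]
  src <- design$row_map$source
  dup <- design$row_map$duplicate
  obs <- design$design$values[src, primary]
  draws <- vapply(imp$completed, function(w) w[dup, primary],
                  numeric(length(dup)))
  draws <- matrix(draws, nrow = length(dup))
  structure(
    list(obs = obs, draws = draws,
         kind = design$design$var_kinds[[primary]], target = primary),
    class = "replicate_matrix"
  )
}

#' @export
print.replicate_matrix <- function(x, ...) {
  cat(sprintf("Replicate matrix for '%s' (%s): %d observed values x %d draws\n",
              x$target, x$kind, length(x$obs), ncol(x$draws)))
  invisible(x)
}

#' Summarize observed values against their replicate draws
#'
#' For each observed value, the per-point nominal interval is formed from the
#' empirical `alpha/2` and `1 - alpha/2` quantiles of its `m` replicate draws
#' (midpoint interpolation on the order statistics, quantile type 5) and the
#' center is the replicate mean. Aggregates:
#' \describe{
#'   \item{COV}{fraction of observed values inside their interval,}
#'   \item{Distance}{mean absolute distance between observed values and
#'     replicate means,}
#'   \item{CIW}{mean interval width.}
#' }
#'
#' @param rep A `replicate_matrix`.
#' @param level Nominal coverage level in (0, 1), e.g. 0.95.
#' @return An object of class `replicate_summary`: list with `level`,
#'   per-point `lower`, `upper`, `center`, `covered`, `obs`, and aggregates
#'   `cov`, `distance`, `ciw`.
#' @export
summarize_replicates <- function(rep, level = 0.95) {
  stopifnot(inherits(rep, "replicate_matrix"))
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  if (ncol(rep$draws) < 2L) stop("need m >= 2 replicate draws")
  if (!all(is.finite(rep$draws)) || !all(is.finite(rep$obs))) {
    stop("replicate draws and observed values must be finite")
  }
  alpha <- 1 - level
  probs <- c(alpha / 2, 1 - alpha / 2)
  qs <- t(apply(rep$draws, 1L, quantile, probs = probs, type = 5,
                names = FALSE))
  lower <- qs[, 1L]; upper <- qs[, 2L]
  center <- rowMeans(rep$draws)
  covered <- rep$obs >= lower & rep$obs <= upper
  structure(
    list(level = level, obs = rep$obs, lower = lower, upper = upper,
         center = center, covered = covered,
         cov = mean(covered),
         distance = mean(abs(rep$obs - center)),
         ciw = mean(upper - lower)),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary at %g%% nominal level (%d points)\n",
              100 * x$level, length(x$obs)))
  cat(sprintf("  COV = %.3f   Distance = %.3f   CIW = %.3f\n",
              x$cov, x$distance, x$ciw))
  invisible(x)
}

# Clipped per-point replicate probabilities for a binary target:
# rowwise mean of the 0/1 draws, clipped to [1/(2m), 1 - 1/(2m)] so the
# deviance stays finite at finite m.
replicate_probs <- function(rep) {
  m <- ncol(rep$draws)
  pmin(pmax(rowMeans(rep$draws), 1 / (2 * m)), 1 - 1 / (2 * m))
}

#' Mean squared deviance of a binary target against its replicates
#'
#' For each observed binary value y with clipped replicate probability
#' \eqn{\tilde p}, the squared deviance residual is
#' \eqn{d^2 = -2[y \log\tilde p + (1 - y)\log(1 - \tilde p)]}; the statistic
#' is the mean of \eqn{d^2} over the observed points (the sum of squared
#' deviances divided by the sample size). Smaller values indicate replicate
#' probabilities that track the observed outcomes better.
#'
#' @param rep A `replicate_matrix` with `kind == "binary"`.
#' @return A single number.
#' @export
mean_squared_deviance <- function(rep) {
  stopifnot(inherits(rep, "replicate_matrix"))
  if (rep$kind != "binary") stop("deviance requires a binary target")
  if (!all(rep$obs %in% c(0, 1)) || !all(rep$draws %in% c(0, 1))) {
    stop("observed values and draws must be 0/1")
  }
  p <- replicate_probs(rep)
  d2 <- -2 * (rep$obs * log(p) + (1 - rep$obs) * log1p(-p))
  mean(d2)
}

#' Signed deviance residuals of a binary target
#'
#' @inheritParams mean_squared_deviance
#' @return Numeric vector, one signed residual
#'   \eqn{\mathrm{sign}(y - \tilde p)\sqrt{d^2}} per observed point.
#' @export
deviance_residuals <- function(rep) {
  stopifnot(inherits(rep, "replicate_matrix"))
  if (rep$kind != "binary") stop("deviance requires a binary target")
  p <- replicate_probs(rep)
  d2 <- -2 * (rep$obs * log(p) + (1 - rep$obs) * log1p(-p))
  sign(rep$obs - p) * sqrt(d2)
}

#' One-call posterior predictive check of an imputation model
#'
#' Glue for the whole diagnostic: builds the over-imputation design for
#' `target`, multiply imputes it with the requested methods, extracts the
#' replicate matrix, and summarises it at each nominal level (plus the mean
#' squared deviance for binary targets).
#'
#' @inheritParams build_overimputation_design
#' @param spec Optional [method_spec()]; default [default_method_spec()] on
#'   the design.
#' @param m Number of imputations.
#' @param n_iter FCS sweeps (default as in [fcs_impute()]).
#' @param levels Nominal interval levels to report.
#' @param seed Integer master seed (recorded in the result).
#' @return An object of class `ppc_check`: list with `target`, `rep`
#'   (`replicate_matrix`), `summaries` (one `replicate_summary` per level),
#'   `deviance` (binary targets only), `design`, `imp`, and `config`.
#' @examples
#' d <- gen_quadratic_outcome(150, seed = 1)
#' inc <- ampute(d, amputation_spec("y", 0.3, "MCAR", seed = 2))
#' chk <- overimpute_check(inc, "y", m = 20, seed = 3)
#' chk
#' @export
overimpute_check <- function(data, target, spec = NULL, m = 50L,
                             n_iter = NULL, levels = 0.95, seed = NULL) {
  data <- as_incomplete_data(data)
  design <- build_overimputation_design(data, target)
  if (is.null(spec)) spec <- default_method_spec(design$design, design$where)
  imp <- fcs_impute(design$design, spec, where = design$where, m = m,
                    n_iter = n_iter, seed = seed)
  rep <- replicate_matrix(imp, design)
  summaries <- lapply(levels, function(l) summarize_replicates(rep, l))
  names(summaries) <- paste0("level_", levels)
  dev <- if (rep$kind == "binary") mean_squared_deviance(rep) else NULL
  structure(
    list(target = design$target, rep = rep, summaries = summaries,
         deviance = dev, design = design, imp = imp,
         config = list(target = target, m = m, levels = levels,
                       n_iter = imp$iterations, seed = seed,
                       methods = spec$methods, donors = spec$donors)),
    class = "ppc_check"
  )
}

#' @export
print.ppc_check <- function(x, ...) {
  cat("Posterior predictive check for '", x$target[1L], "' (m = ",
      x$imp$m, ")\n", sep = "")
  for (s in x$summaries) {
    cat(sprintf("  %4.0f%%: COV = %.3f  Distance = %.3f  CIW = %.3f\n",
                100 * s$level, s$cov, s$distance, s$ciw))
  }
  if (!is.null(x$deviance)) {
    cat(sprintf("  mean squared deviance = %.3f\n", x$deviance))
  }
  invisible(x)
}
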