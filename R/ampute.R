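#' Amputation specification
#'
#' Describes how missingness is generated in complete data: which columns are
#' blanked together (`pattern`), the target proportion of incomplete cases,
#' the mechanism, and the weights of the weighted sum score that drives
#' missingness under MAR.
#'
#' @param pattern Character vector of columns made missing together.
#' @param prop Target proportion of incomplete cases, strictly in (0, 1).
#' @param mechanism `"MCAR"` (score-independent) or `"MARr"` (right-tailed
#'   MAR: higher weighted sum score, higher missingness probability).
#' @param weights Named numeric weights over columns disjoint from `pattern`
#'   (the score is computed from the observed-side variables). Required for
#'   `"MARr"`.
#' @param slope Logistic slope `b` on the standardized score under `"MARr"`.
#' @param seed Optional integer seed used by [ampute()].
#' @return An object of class `amputation_spec`.
#' @export
amputation_spec <- function(pattern, prop, mechanism = c("MCAR", "MARr"),
                            weights = NULL, slope = 1, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(prop) || prop <= 0 || prop >= 1) {
    stop("`prop` must lie strictly between 0 and 1")
  }
  if (mechanism == "MARr") {
    if (is.null(weights) || is.null(names(weights))) {
      stop('mechanism "MARr" needs named `weights`')
    }
    if (all(weights == 0)) stop("all-zero weights cannot drive MARr")
    if (length(intersect(names(weights), pattern))) {
      stop("weight columns must be disjoint from the pattern columns")
    }
  }
  structure(
    list(pattern = pattern, prop = prop, mechanism = mechanism,
         weights = weights, slope = slope, seed = seed),
    class = "amputation_spec"
  )
}

#' Weighted sum score
#'
#' Per-row linear combination \eqn{w^\top x} of complete covariates,
#' standardized to mean 0 and SD 1 by default. Because of the
#' standardization only relative weights matter: doubling all weights leaves
#' the score — and hence the missingness allocation — unchanged.
#'
#' @param data Complete data (matrix or data frame).
#' @param weights Named numeric weights over columns of `data`.
#' @param standardize Standardize the scores? Default `TRUE`.
#' @return Numeric vector of per-row scores.
#' @export
weighted_sum_score <- function(data, weights, standardize = TRUE) {
  data <- if (inherits(data, "incomplete_data")) data$values else
    as.matrix(as.data.frame(data))
  cols <- names(weights)
  if (!all(cols %in% colnames(data))) {
    stop("weight columns absent from the data: ",
         paste(setdiff(cols, colnames(data)), collapse = ", "))
  }
  sub <- data[, cols, drop = FALSE]
  if (anyNA(sub)) stop("weighted columns must be complete")
  score <- drop(sub %*% weights)
  if (standardize) {
    s <- sd(score)
    if (s == 0) stop("weighted sum score is constant; cannot standardize")
    score <- (score - mean(score)) / s
  }
  score
}

#' Generate missingness in complete data
#'
#' Selects rows to make incomplete and blanks all `pattern` columns jointly
#' in those rows. Under MCAR each row is incomplete independently with
#' probability `prop`. Under MARr the row-wise probability is
#' \eqn{\mathrm{logit}^{-1}(a + b\cdot wss)} with fixed slope `b > 0` on the
#' standardized weighted sum score and intercept `a` solved numerically so
#' that the mean probability equals `prop` — rows with a higher score are
#' more likely to be unobserved.
#'
#' @param data Complete data (matrix or data frame), complete at least in the
#'   pattern and weight columns.
#' @param spec An [amputation_spec()].
#' @return An `incomplete_data` object with attribute `"amputed_rows"`
#'   (logical vector of the realized incomplete rows).
#' @examples
#' d <- gen_quadratic_outcome(500, seed = 1)
#' inc <- ampute(d, amputation_spec("y", 0.3, "MARr",
#'                                  weights = c(x = 1), seed = 2))
#' mean(attr(inc, "amputed_rows"))
#' @export
ampute <- function(data, spec) {
  stopifnot(inherits(spec, "amputation_spec"))
  df <- as.data.frame(data)
  if (!all(spec$pattern %in% names(df))) {
    stop("pattern columns absent from the data: ",
         paste(setdiff(spec$pattern, names(df)), collapse = ", "))
  }
  if (anyNA(df[spec$pattern])) stop("pattern columns must start complete")
  n <- nrow(df)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$mechanism == "MCAR") {
    p_miss <- rep(spec$prop, n)
  } else {
    wss <- weighted_sum_score(df, spec$weights)
    b <- spec$slope
    f <- function(a) mean(plogis(a + b * wss)) - spec$prop
    sol <- tryCatch(uniroot(f, c(-50, 50), tol = 1e-10),
                    error = function(e) {
                      stop("could not bracket the MARr intercept: ",
                           conditionMessage(e))
                    })
    p_miss <- plogis(sol$root + b * wss)
  }
  amputed <- runif(n) < p_miss
  df[amputed, spec$pattern] <- NA
  out <- incomplete_data(df)
  attr(out, "amputed_rows") <- amputed
  out
}
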