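#' Per-variable imputation method specification
#'
#' Assigns an imputation method to each variable and declares which variables
#' may enter each conditional model. Methods:
#' \describe{
#'   \item{`"norm"`}{Bayesian normal-linear regression (continuous).}
#'   \item{`"pmm"`}{Predictive mean matching, type-1 matching (continuous).}
#'   \item{`"logreg"`}{Bayesian logistic regression (binary).}
#'   \item{`"pc"`}{Polynomial combination for a jointly missing
#'     \eqn{(X, X^2)} pair under the quadratic substantive model (set on both
#'     columns; requires `quadratic`).}
#'   \item{`"smcfcs"`}{Substantive-model-compatible rejection sampling for the
#'     same quadratic setting (set on both columns; requires `quadratic`).}
#'   \item{`"none"`}{Variable is never imputed (must be fully observed and not
#'     over-imputed).}
#' }
#'
#' @param methods Named character vector, one method per variable.
#' @param predictors Logical p x p matrix; `predictors[j, k]` is `TRUE` when
#'   variable `k` may predict variable `j`. Default: every other variable.
#'   The diagonal is forced to `FALSE` (no variable predicts itself).
#' @param donors Donor-pool size for PMM-type matching (default 5).
#' @param quadratic For `"pc"`/`"smcfcs"`: a list
#'   `list(x = , x2 = , y = )` naming the linear term, its exact square, and
#'   the outcome of the quadratic substantive model.
#' @param max_reject Proposal cap per cell for `"smcfcs"` rejection sampling.
#' @param max_redraw Re-draw cap for negative discriminants in `"pc"`.
#'
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(methods, predictors = NULL, donors = 5L,
                        quadratic = NULL, max_reject = 100000L,
                        max_redraw = 100L) {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("`methods` must be a fully named character vector")
  }
  known <- c("norm", "pmm", "logreg", "pc", "smcfcs", "none")
  bad <- setdiff(unique(methods), known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  p <- length(methods)
  vars <- names(methods)
  if (is.null(predictors)) {
    predictors <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  }
  if (!is.matrix(predictors) || !identical(dim(predictors), c(p, p))) {
    stop("`predictors` must be a ", p, " x ", p, " logical matrix")
  }
  if (is.null(rownames(predictors))) dimnames(predictors) <- list(vars, vars)
  diag(predictors) <- FALSE
  if (donors < 1L) stop("`donors` must be a positive integer")
  uses_quad <- any(methods %in% c("pc", "smcfcs"))
  if (uses_quad) {
    if (is.null(quadratic) ||
        !all(c("x", "x2", "y") %in% names(quadratic))) {
      stop('methods "pc"/"smcfcs" need `quadratic = list(x=, x2=, y=)`')
    }
    qv <- unlist(quadratic[c("x", "x2", "y")])
    if (!all(qv %in% vars)) stop("quadratic block names not among variables")
    if (!identical(methods[[quadratic$x]], methods[[quadratic$x2]])) {
      stop("the x and x2 columns of the quadratic block must share a method")
    }
  }
  structure(
    list(methods = methods, predictors = predictors,
         donors = as.integer(donors), quadratic = quadratic,
         max_reject = as.integer(max_reject),
         max_redraw = as.integer(max_redraw)),
    class = "method_spec"
  )
}

#' Default method specification for a dataset
#'
#' Incomplete (or over-imputed) continuous variables get `"pmm"`, binary ones
#' `"logreg"`; fully observed, never-over-imputed variables get `"none"`.
#'
#' @param data An `incomplete_data` object (or coercible).
#' @param where Optional logical over-imputation mask (see [fcs_impute()]).
#' @param default_continuous Method for continuous incomplete variables.
#' @inheritParams method_spec
#' @return A `method_spec`.
#' @export
default_method_spec <- function(data, where = NULL,
                                default_continuous = "pmm", donors = 5L) {
  data <- as_incomplete_data(data)
  needs <- !data$observed
  if (!is.null(where)) needs <- needs | where
  methods <- ifelse(
    colSums(needs) > 0L,
    ifelse(data$var_kinds == "binary", "logreg", default_continuous),
    "none"
  )
  names(methods) <- data$var_names
  method_spec(methods, donors = donors)
}

#' @export
print.method_spec <- function(x, ...) {
  cat("Imputation method spec:\n")
  cat(" ", paste(names(x$methods), x$methods, sep = " = ", collapse = ", "),
      "\n")
  if (!is.null(x$quadratic)) {
    cat("  quadratic block:", x$quadratic$x, "+", x$quadratic$x2,
        "given", x$quadratic$y, "\n")
  }
  cat("  pmm donors:", x$donors, "\n")
  invisible(x)
}
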