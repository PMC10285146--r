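#' Multiple imputation by fully conditional specification
#'
#' A compact chained-equations engine. Each of `m` imputation streams starts
#' from a random fill (draws from each variable's observed values) and then
#' sweeps the incomplete variables in column order `n_iter` times. At each
#' visit the conditional model for variable j is refitted on the rows where j
#' is *genuinely* observed — cells marked for over-imputation never
#' contribute to fitting — parameters are drawn from their posterior, and all
#' marked cells of j are redrawn from the posterior predictive distribution.
#'
#' The `where` mask generalises the missingness mask: every genuinely missing
#' cell is always imputed, and observed cells may additionally be marked so
#' that observed values receive replicate draws (over-imputation), the basis
#' of the posterior predictive diagnostics in [overimpute_check()].
#'
#' Streams use independent seed-derived RNG substreams, so results are
#' reproducible for a fixed `seed` and the first streams are unchanged when
#' `m` grows.
#'
#' @param data An `incomplete_data` object (or coercible).
#' @param spec A [method_spec()]; default [default_method_spec()].
#' @param where Optional logical n x p mask of cells to (over)impute; cells
#'   missing in `data` are always included. Default: the missingness mask.
#' @param m Number of imputations (streams).
#' @param n_iter FCS sweeps per stream; default 5 when two or more variables
#'   have marked cells, else 1. When a single variable is imputed there is no
#'   cross-variable feedback and one sweep already draws from the correct
#'   distribution, so extra sweeps are skipped.
#' @param seed Optional integer master seed.
#' @return An object of class `mimp`: list with `m`, `completed` (list of m
#'   completed matrices), `where`, `seed`, `iterations`, `data`, `spec`.
#' @examples
#' d <- gen_quadratic_outcome(200, seed = 1)
#' d$y[1:40] <- NA
#' imp <- fcs_impute(d, m = 3, seed = 7)
#' imp
#' @export
fcs_impute <- function(data, spec = NULL, where = NULL, m = 5L,
                       n_iter = NULL, seed = NULL) {
  data <- as_incomplete_data(data)
  if (m < 1L) stop("`m` must be >= 1")
  vals <- data$values
  n <- nrow(vals); p <- ncol(vals)
  if (is.null(where)) {
    where <- !data$observed
  } else {
    if (!is.logical(where) || !identical(dim(where), dim(vals))) {
      stop("`where` must be a logical matrix matching the data")
    }
    where <- where | !data$observed
  }
  colnames(where) <- colnames(vals)
  if (is.null(spec)) spec <- default_method_spec(data, where)
  if (!inherits(spec, "method_spec")) stop("`spec` must be a method_spec")
  if (!identical(sort(names(spec$methods)), sort(colnames(vals)))) {
    stop("method spec variables do not match the data")
  }

  marked <- colSums(where) > 0L
  # "none" exactly for untouched variables
  none <- spec$methods[colnames(vals)] == "none"
  if (any(marked & none)) {
    stop("variable(s) need imputation but have method \"none\": ",
         paste(colnames(vals)[marked & none], collapse = ", "))
  }
  if (any(!marked & !none)) {
    stop("fully observed, never over-imputed variable(s) must use ",
         "method \"none\": ",
         paste(colnames(vals)[!marked & !none], collapse = ", "))
  }

  visit <- which(marked)
  quad <- spec$quadratic
  if (!is.null(quad) &&
      spec$methods[[quad$x]] %in% c("pc", "smcfcs")) {
    # the block is imputed at the x visit; skip the x2 column
    visit <- setdiff(visit, match(quad$x2, colnames(vals)))
  }
  if (is.null(n_iter)) n_iter <- if (length(visit) >= 2L) 5L else 1L
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  # with a single visited variable there is no cross-variable feedback:
  # each sweep refits the same model on the same genuinely observed rows,
  # so one sweep already draws from the correct distribution and further
  # sweeps are skipped
  if (length(visit) == 1L) n_iter <- 1L

  # rows usable for fitting each variable: genuinely observed, not marked
  fit_rows <- lapply(seq_len(p), function(j) {
    which(data$observed[, j] & !where[, j])
  })
  for (j in visit) {
    if (length(fit_rows[[j]]) == 0L) {
      stop("variable '", colnames(vals)[j],
           "' has no genuinely observed cases to fit on")
    }
  }

  if (!is.null(seed)) set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max, m)

  completed <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(stream_seeds[i])
    work <- vals
    # initial fill: random draws from the observed values of each variable
    for (j in which(marked)) {
      pool <- vals[fit_rows[[j]], j]
      tgt <- which(where[, j])
      work[tgt, j] <- pool[sample.int(length(pool), length(tgt),
                                      replace = TRUE)]
    }
    for (t in seq_len(n_iter)) {
      for (j in visit) {
        work <- impute_one_variable(work, j, data, spec, where,
                                    fit_rows[[j]])
      }
    }
    completed[[i]] <- work
  }

  structure(
    list(m = m, completed = completed, where = where,
         seed = if (is.null(seed)) NA_integer_ else seed,
         iterations = n_iter, data = data, spec = spec),
    class = "mimp"
  )
}

# One FCS visit: refit the conditional model for column j and redraw all
# marked cells. `work` carries the current completed values.
impute_one_variable <- function(work, j, data, spec, where, fr) {
  vars <- colnames(work)
  method <- spec$methods[[vars[j]]]
  tgt <- which(where[, j])

  if (method %in% c("pc", "smcfcs")) {
    quad <- spec$quadratic
    yv <- work[, quad$y]
    x_obs <- work[fr, quad$x]
    y_obs <- yv[fr]
    pair <- if (method == "pc") {
      impute_pc(y_obs, x_obs, yv[tgt], donors = spec$donors,
                max_redraw = spec$max_redraw)
    } else {
      impute_smcfcs_quadratic(y_obs, x_obs, yv[tgt],
                              max_reject = spec$max_reject)
    }
    work[tgt, quad$x] <- pair[, "x"]
    work[tgt, quad$x2] <- pair[, "x2"]
    return(work)
  }

  preds <- which(spec$predictors[vars[j], vars])
  # predictors must be filled wherever used
  used <- c(fr, tgt)
  if (length(preds) && anyNA(work[used, preds])) {
    holes <- preds[colSums(is.na(work[used, preds, drop = FALSE])) > 0L]
    stop("predictor(s) never filled when imputing '", vars[j], "': ",
         paste(vars[holes], collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, work[, preds, drop = FALSE])
  y_obs <- work[fr, j]
  work[tgt, j] <- switch(
    method,
    norm = impute_normal(y_obs, X[fr, , drop = FALSE],
                         X[tgt, , drop = FALSE]),
    pmm = impute_pmm(y_obs, X[fr, , drop = FALSE],
                     X[tgt, , drop = FALSE], donors = spec$donors),
    logreg = impute_logistic(y_obs, X[fr, , drop = FALSE],
                             X[tgt, , drop = FALSE]),
    stop("unsupported method: ", method)
  )
  work
}

#' @export
print.mimp <- function(x, ...) {
  cat(sprintf("Multiple imputations: m = %d, %d x %d data, %d marked cells, %d iteration(s)\n",
              x$m, nrow(x$data$values), ncol(x$data$values),
              sum(x$where), x$iterations))
  meth <- x$spec$methods[x$spec$methods != "none"]
  cat("  methods:", paste(names(meth), meth, sep = " = ", collapse = ", "),
      "\n")
  if (!is.na(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Extract a completed dataset
#' @param imp A `mimp` object from [fcs_impute()].
#' @param i Imputation index in `1:m`.
#' @return A data frame with all marked cells filled.
#' @export
complete_data <- function(imp, i = 1L) {
  stopifnot(inherits(imp, "mimp"), i >= 1L, i <= imp$m)
  as.data.frame(imp$completed[[i]])
}
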