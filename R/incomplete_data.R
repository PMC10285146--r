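#' Incomplete rectangular dataset
#'
#' Container for a numeric data matrix with missing cells, the backbone of all
#' imputation and diagnostic operations in the package. Cells are either
#' observed (finite numbers) or unobserved (`NA`). Each variable is classed as
#' `"continuous"` or `"binary"`; binary variables may only take values 0/1
#' where observed.
#'
#' @param values A numeric matrix or data frame; missing cells coded `NA`.
#' @param var_kinds Optional character vector (one per column) with entries
#'   `"continuous"` or `"binary"`. By default a column whose observed values
#'   are all in \{0, 1\} is classed binary.
#'
#' @return An object of class `incomplete_data`: a list with elements
#'   `values` (numeric matrix, `NA` for unobserved), `observed` (logical
#'   matrix, `TRUE` = observed), `var_names`, and `var_kinds`.
#' @examples
#' d <- incomplete_data(data.frame(x = c(1, 2, NA), y = c(0, 1, 1)))
#' d$var_kinds
#' @export
incomplete_data <- function(values, var_kinds = NULL) {
  if (is.data.frame(values)) {
    non_num <- !vapply(values, is.numeric, logical(1))
    if (any(non_num)) {
      stop("non-numeric column(s): ", paste(names(values)[non_num], collapse = ", "))
    }
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or data frame")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  observed <- !is.na(values)
  if (any(observed & !is.finite(values))) {
    stop("observed cells must be finite")
  }
  p <- ncol(values)
  if (is.null(var_kinds)) {
    var_kinds <- vapply(seq_len(p), function(j) {
      v <- values[observed[, j], j]
      if (length(v) > 0L && all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  } else {
    var_kinds <- rep_len(var_kinds, p)
    if (!all(var_kinds %in% c("continuous", "binary"))) {
      stop('var_kinds must be "continuous" or "binary"')
    }
    for (j in which(var_kinds == "binary")) {
      v <- values[observed[, j], j]
      if (!all(v %in% c(0, 1))) {
        stop("binary variable '", colnames(values)[j],
             "' has observed values outside {0, 1}")
      }
    }
  }
  names(var_kinds) <- colnames(values)
  structure(
    list(values = values, observed = observed,
         var_names = colnames(values), var_kinds = var_kinds),
    class = "incomplete_data"
  )
}

#' Coerce to an incomplete dataset
#' @param x A matrix, data frame, or `incomplete_data` object.
#' @param ... Passed to [incomplete_data()].
#' @return An `incomplete_data` object.
#' @export
as_incomplete_data <- function(x, ...) {
  if (inherits(x, "incomplete_data")) return(x)
  incomplete_data(x, ...)
}

#' @export
print.incomplete_data <- function(x, ...) {
  n <- nrow(x$values); p <- ncol(x$values)
  nmis <- sum(!x$observed)
  cat(sprintf("Incomplete dataset: %d rows x %d variables, %d missing cells (%.1f%%)\n",
              n, p, nmis, 100 * nmis / (n * p)))
  per_var <- colSums(!x$observed)
  kinds <- paste0(x$var_names, " (", substr(x$var_kinds, 1, 4), ", ",
                  per_var, " NA)")
  cat(" ", paste(kinds, collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.incomplete_data <- function(x) dim(x$values)

#' @export
as.data.frame.incomplete_data <- function(x, ...) {
  as.data.frame(x$values, ...)
}

#' Number of observed cases of a variable
#' @param data An `incomplete_data` object.
#' @param var Variable name.
#' @return Integer count of rows observed on `var`.
#' @export
n_observed <- function(data, var) {
  data <- as_incomplete_data(data)
  sum(data$observed[, var])
}
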