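#' Read an incomplete dataset from CSV
#'
#' Rectangular CSV with a header row; the listed markers (and empty cells)
#' parse as missing. All columns must be numeric; a column whose observed
#' values are all 0/1 is auto-detected as binary unless overridden.
#'
#' @param path CSV file path.
#' @param na_markers Strings treated as missing (default `"NA"` and empty).
#' @param var_kinds Optional per-column override for [incomplete_data()].
#' @return An `incomplete_data` object.
#' @export
read_incomplete_csv <- function(path, na_markers = c("NA", ""),
                                var_kinds = NULL) {
  df <- utils::read.csv(path, na.strings = na_markers,
                        check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num)) {
    j <- which(non_num)[1L]
    bad <- which(!is.na(df[[j]]) &
                   is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
    stop("non-numeric cell in column '", names(df)[j], "', row ",
         if (is.na(bad)) "?" else bad)
  }
  incomplete_data(df, var_kinds = var_kinds)
}

#' Write an incomplete dataset to CSV
#'
#' Missing cells are written as `NA`; a read back with
#' [read_incomplete_csv()] reproduces values and mask exactly.
#'
#' @param data An `incomplete_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incomplete_csv <- function(data, path) {
  data <- as_incomplete_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' Export completed datasets in long format
#'
#' Stacks the `m` completed copies with a leading `.imp` index column
#' (1..m), one long CSV.
#'
#' @param imp A `mimp` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_imputations <- function(imp, path) {
  stopifnot(inherits(imp, "mimp"))
  long <- do.call(rbind, lapply(seq_len(imp$m), function(i) {
    cbind(data.frame(.imp = i), as.data.frame(imp$completed[[i]]))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a diagnostic report to disk
#'
#' Emits `report.json` (aggregate metrics, the configuration echo including
#' the seed — enough for a bit-exact re-run) and `points.csv` (the per-point
#' interval table, one row per observed value of the target).
#'
#' @param check A `ppc_check` from [overimpute_check()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(check, dir) {
  stopifnot(inherits(check, "ppc_check"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summaries <- lapply(check$summaries, function(s) {
    list(level = s$level, cov = s$cov, distance = s$distance, ciw = s$ciw)
  })
  report <- list(
    target = check$target,
    n_points = length(check$rep$obs),
    kind = check$rep$kind,
    summaries = summaries,
    deviance = check$deviance,
    config = check$config
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  s1 <- check$summaries[[1L]]
  pts <- data.frame(point = seq_along(s1$obs), obs = s1$obs,
                    center = s1$center, lower = s1$lower,
                    upper = s1$upper, covered = s1$covered)
  csv_path <- file.path(dir, "points.csv")
  utils::write.csv(pts, csv_path, row.names = FALSE)
  invisible(c(report = json_path, points = csv_path))
}
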