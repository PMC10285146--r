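# Graphical diagnostics. Every plot builds on a plain data table that is
# also returned (or obtainable via the *_data helpers), so the visual
# claims are testable without parsing images.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_density
#'   facet_wrap labs scale_colour_manual theme_minimal ggsave
NULL

#' Data behind the distribution plot
#'
#' @param summary A `replicate_summary`.
#' @return A tibble sorted in ascending order of the replicate mean, with
#'   columns `rank`, `center`, `lower`, `upper`, `obs`, `covered`.
#' @export
distribution_plot_data <- function(summary) {
  stopifnot(inherits(summary, "replicate_summary"))
  o <- order(summary$center)
  tibble::tibble(rank = seq_along(o),
                 center = summary$center[o],
                 lower = summary$lower[o],
                 upper = summary$upper[o],
                 obs = summary$obs[o],
                 covered = summary$covered[o])
}

#' Distribution plot of per-point predictive intervals
#'
#' Observed values plotted against the rank of their replicate means, with
#' the interval bounds as grey lines. Points falling inside their nominal
#' interval are drawn in blue, points falling outside in red; under a
#' well-fitting imputation model the red points spread without positional
#' pattern, while misfit concentrates them in particular regions.
#'
#' @param summary A `replicate_summary`.
#' @param file Optional output path (PNG/SVG via [ggplot2::ggsave()]).
#' @param in_colour,out_colour Colours for covered / non-covered points.
#' @return The ggplot object, invisibly if written to `file`.
#' @export
distribution_plot <- function(summary, file = NULL,
                              in_colour = "#3366CC", out_colour = "#CC3333") {
  d <- distribution_plot_data(summary)
  p <- ggplot(d, aes(x = rank)) +
    geom_line(aes(y = lower), colour = "grey55") +
    geom_line(aes(y = upper), colour = "grey55") +
    geom_point(aes(y = obs, colour = covered), size = 0.8) +
    scale_colour_manual(values = c(`TRUE` = in_colour,
                                   `FALSE` = out_colour),
                        labels = c(`TRUE` = "inside", `FALSE` = "outside"),
                        name = sprintf("%g%% interval",
                                       100 * summary$level)) +
    labs(x = "rank of replicate mean", y = "observed value") +
    theme_minimal()
  if (!is.null(file)) {
    ggsave(file, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Long-format table of observed and replicate values
#'
#' @param rep A `replicate_matrix`.
#' @param covariate Optional covariate vector (length n_obs) for scatter
#'   panels.
#' @param m_show Number of imputations to include (default `min(5, m)`).
#' @return A tibble with columns `imp` (0 = observed), `value`, `covariate`,
#'   `role` (`"observed"`/`"replicate"`), `point` (observation index).
#' @export
comparison_plot_data <- function(rep, covariate = NULL, m_show = 5L) {
  stopifnot(inherits(rep, "replicate_matrix"))
  m_show <- min(m_show, ncol(rep$draws))
  n <- length(rep$obs)
  if (is.null(covariate)) covariate <- rep(NA_real_, n)
  stopifnot(length(covariate) == n)
  blocks <- vector("list", m_show + 1L)
  blocks[[1L]] <- tibble::tibble(imp = 0L, point = seq_len(n),
                                 value = rep$obs, covariate = covariate,
                                 role = "observed")
  for (i in seq_len(m_show)) {
    blocks[[i + 1L]] <- tibble::tibble(imp = i, point = seq_len(n),
                                       value = rep$draws[, i],
                                       covariate = covariate,
                                       role = "replicate")
  }
  do.call(rbind, blocks)
}

#' Density and scatter comparison of observed vs replicated data
#'
#' The density panel overlays the kernel density of the observed target
#' (blue) with one density per shown imputation (red); the scatter panel
#' shows the observed values (panel 0) and, per imputation, observed and
#' replicate values against a covariate. A congenial imputation model makes
#' the replicate densities and point clouds overlap the observed ones.
#' Bandwidths use Silverman's rule (the [stats::density()] default).
#'
#' @inheritParams comparison_plot_data
#' @param file Optional path *prefix*; writes `<prefix>_density.png` and
#'   `<prefix>_scatter.png`.
#' @return List with ggplot objects `density` and `scatter` (scatter `NULL`
#'   without a covariate), the `data` table, and any written `files`.
#' @export
comparison_plots <- function(rep, covariate = NULL, m_show = 5L,
                             file = NULL) {
  d <- comparison_plot_data(rep, covariate, m_show)
  dens <- ggplot(d, aes(x = value, group = imp, colour = role)) +
    geom_density(bw = "nrd0") +
    scale_colour_manual(values = c(observed = "#3366CC",
                                   replicate = "#CC3333")) +
    labs(x = rep$target, y = "density") +
    theme_minimal()
  scat <- NULL
  if (!all(is.na(d$covariate))) {
    scat <- ggplot(d, aes(x = covariate, y = value, colour = role)) +
      geom_point(size = 0.6, alpha = 0.7) +
      facet_wrap(~imp, nrow = 1L) +
      scale_colour_manual(values = c(observed = "#3366CC",
                                     replicate = "#CC3333")) +
      labs(x = "covariate", y = rep$target) +
      theme_minimal()
  }
  files <- character(0)
  if (!is.null(file)) {
    f1 <- paste0(file, "_density.png")
    ggsave(f1, dens, width = 6, height = 4, dpi = 150)
    files <- f1
    if (!is.null(scat)) {
      f2 <- paste0(file, "_scatter.png")
      ggsave(f2, scat, width = 9, height = 3.2, dpi = 150)
      files <- c(files, f2)
    }
  }
  list(density = dens, scatter = scat, data = d, files = files)
}

#' Deviance-residual plot for a binary target
#'
#' Signed deviance residuals of the observed binary values against their
#' clipped replicate probabilities, plotted against the observation index
#' (or a supplied linear predictor). Residuals near zero indicate replicate
#' probabilities that track the observed outcomes.
#'
#' @param rep A `replicate_matrix` with `kind == "binary"`.
#' @param x Optional x-axis values (e.g. a linear predictor); default index.
#' @param file Optional output path.
#' @return The ggplot object (invisibly if written), with the residual table
#'   in attribute `"data"`.
#' @export
deviance_plot <- function(rep, x = NULL, file = NULL) {
  res <- deviance_residuals(rep)
  if (is.null(x)) x <- seq_along(res)
  d <- tibble::tibble(x = x, residual = res,
                      obs = rep$obs)
  p <- ggplot(d, aes(x = x, y = residual)) +
    geom_point(size = 0.7, alpha = 0.7, colour = "#3366CC") +
    labs(x = if (is.null(x)) "index" else "x", y = "deviance residual") +
    theme_minimal()
  attr(p, "data") <- d
  if (!is.null(file)) {
    ggsave(file, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
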