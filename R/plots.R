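#' Plot one stratum's prevalence trend
#'
#' Draws, in prevalence space, the per-wave points `(P(1), P(0))` labeled by
#' year, their closed 95% confidence-region curves, the fitted trend line
#' extended to its first axis crossing, and the eradication markers at
#' `(threshold, 0)` and `(0, threshold)` (the "<5% in both groups" corner).
#' Axes share a common scale starting at 0, so the identity diagonal is the
#' locus of perfect equality between the SES extremes.
#'
#' @param points Tibble of per-wave point estimates with columns `year`,
#'   `p1`, `p0`.
#' @param regions List of [confidence_region()] curves, one per wave (may be
#'   empty).
#' @param line A [fit_trend()] line, or `NULL` to fit from `points`.
#' @param threshold Eradication cutoff (default 0.05).
#' @return A ggplot object.
#' @export
plot_trend <- function(points, regions = list(), line = NULL, threshold = 0.05) {
  check_columns(points, c("year", "p1", "p0"))
  if (nrow(points) < 2) {
    rlang::abort("plot_trend() needs at least 2 waves", class = "ineqtrend_input_error")
  }
  if (is.null(line)) line <- fit_trend(points)
  cross <- axis_intersection(line)

  region_df <- NULL
  if (length(regions) > 0) {
    region_df <- purrr::imap_dfr(regions, function(r, i) {
      tibble::tibble(wave = as.character(i), p1 = r$p1, p0 = r$p0)
    })
  }

  # line segment from the axis crossing (or the y-axis) to beyond the data
  x_hi <- max(points$p1, region_df$p1 %||% 0, threshold) * 1.1
  x_lo <- if (cross$axis == "x-axis") cross$x else 0
  seg <- tibble::tibble(
    x = c(x_lo, x_hi),
    y = line$intercept + line$slope * c(x_lo, x_hi)
  )
  lim <- max(
    x_hi, points$p0, region_df$p0 %||% 0,
    seg$y, threshold
  ) * 1.05

  p <- ggplot2::ggplot()
  if (!is.null(region_df)) {
    p <- p + ggplot2::geom_path(
      data = region_df,
      ggplot2::aes(x = .data$p1, y = .data$p0, group = .data$wave),
      colour = "grey55", linewidth = 0.4
    )
  }
  p +
    ggplot2::geom_line(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "steelblue", linewidth = 0.7
    ) +
    ggplot2::geom_point(
      data = points, ggplot2::aes(x = .data$p1, y = .data$p0),
      size = 2
    ) +
    ggplot2::geom_text(
      data = points,
      ggplot2::aes(x = .data$p1, y = .data$p0, label = .data$year),
      vjust = -0.9, size = 3
    ) +
    ggplot2::geom_point(
      data = tibble::tibble(x = c(threshold, 0), y = c(0, threshold)),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "forestgreen", size = 3
    ) +
    ggplot2::coord_equal(xlim = c(0, lim), ylim = c(0, lim), expand = FALSE) +
    ggplot2::labs(
      x = "P(1): prevalence at highest SES",
      y = "P(0): prevalence at lowest SES"
    ) +
    ggplot2::theme_minimal()
}

# Assemble plot_trend() inputs for one "region/gender" stratum of a run.
autoplot_stratum <- function(run, label) {
  tr <- run$trends[[label]]
  if (is.null(tr)) {
    rlang::abort(paste0("no trend stratum '", label, "' in this run"))
  }
  waves <- tr$points$year
  keys <- paste(label, waves, sep = "/")
  regions <- run$regions[keys]
  regions <- regions[!vapply(regions, is.null, logical(1))]
  names(regions) <- sub(".*/", "", names(regions))
  plot_trend(tr$points, regions, tr$line, run$config$threshold) +
    ggplot2::ggtitle(label)
}

#' Autoplot a pipeline run
#'
#' @param object An `ineq_run` from [run_pipeline()].
#' @param stratum A `"region/gender"` label; defaults to the first trend
#'   stratum.
#' @param ... Unused.
#' @return A ggplot object (see [plot_trend()]).
#' @export
autoplot.ineq_run <- function(object, stratum = NULL, ...) {
  stratum <- stratum %||% names(object$trends)[1]
  autoplot_stratum(object, stratum)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
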