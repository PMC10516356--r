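#' Fit the trend line of low-SES on high-SES prevalence
#'
#' Ordinary least squares of `p0` (prevalence in the low-SES extreme) on `p1`
#' (prevalence in the high-SES extreme), one point per survey wave,
#' unweighted. The intercept is the estimated low-SES prevalence at the
#' moment the high-SES prevalence reaches zero; it may legitimately be
#' negative, meaning low-SES prevalence would reach zero first.
#'
#' @param points A data frame with columns `p1` and `p0` (and optionally
#'   `year`, used in error messages), at least two rows with distinct `p1`.
#' @return An object of class `trend_line`: list with `slope`, `intercept`,
#'   `n_points`.
#' @examples
#' fit_trend(tibble::tibble(p1 = c(0.1, 0.2, 0.3), p0 = c(0.1, 0.2, 0.3)))
#' @export
fit_trend <- function(points) {
  check_columns(points, c("p1", "p0"))
  if (nrow(points) < 2) {
    rlang::abort("fit_trend() needs at least 2 waves", class = "ineqtrend_input_error")
  }
  p1 <- points$p1
  p0 <- points$p0
  if (max(p1) - min(p1) <= .Machine$double.eps * max(abs(p1), 1)) {
    waves <- if ("year" %in% names(points)) paste(points$year, collapse = ", ") else "all waves"
    rlang::abort(
      paste0("all high-SES prevalences identical (", waves, "); trend line is vertical"),
      class = "ineqtrend_degenerate_error"
    )
  }
  slope <- sum((p1 - mean(p1)) * (p0 - mean(p0))) / sum((p1 - mean(p1))^2)
  structure(
    list(slope = slope, intercept = mean(p0) - slope * mean(p1), n_points = nrow(points)),
    class = "trend_line"
  )
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf(
    "Trend line: p0 = %.4f + %.4f * p1  (%d waves)\n",
    x$intercept, x$slope, x$n_points
  ))
  invisible(x)
}

#' First axis crossing of a trend line in the direction of decline
#'
#' Travelling along the line in the direction of decreasing high-SES
#' prevalence (the direction a declining trend extrapolates to), reports
#' which axis the line meets first: the y-axis at `(0, intercept)` when the
#' intercept is non-negative, or the x-axis at `(-intercept/slope, 0)` when
#' the intercept is negative and the slope positive. A line with negative
#' intercept and non-positive slope leaves the feasible quadrant without a
#' crossing at a non-negative coordinate (`axis = "none"`).
#'
#' @param line A `trend_line`, or anything with `slope` and `intercept`
#'   elements.
#' @return A one-row tibble with `x`, `y` (crossing coordinates, `NA` when
#'   none) and `axis` (`"y-axis"`, `"x-axis"` or `"none"`).
#' @export
axis_intersection <- function(line) {
  s <- line$slope
  b <- line$intercept
  if (b >= 0) {
    tibble::tibble(x = 0, y = b, axis = "y-axis")
  } else if (s > 0) {
    tibble::tibble(x = -b / s, y = 0, axis = "x-axis")
  } else {
    tibble::tibble(x = NA_real_, y = NA_real_, axis = "none")
  }
}

# Vectorized OLS over aligned draw matrices: one line per simulation row.
# Returns slope, intercept and a validity flag (FALSE where p1 is constant).
fit_trend_rows <- function(P1, P0) {
  m1 <- rowMeans(P1)
  m0 <- rowMeans(P0)
  d1 <- P1 - m1
  ss <- rowSums(d1^2)
  spread <- apply(P1, 1, function(r) max(r) - min(r))
  ok <- spread > .Machine$double.eps * pmax(abs(m1), 1)
  slope <- ifelse(ok, rowSums(d1 * (P0 - m0)) / ss, NA_real_)
  list(slope = slope, intercept = m0 - slope * m1, ok = ok)
}

#' Likelihood of eradicating the inequality
#'
#' For every simulation index, fits the trend line through that draw's
#' per-wave prevalence pairs, finds its first axis crossing in the direction
#' of declining prevalence, and counts the line as "eradicating" when the
#' crossing lies within `threshold` of the origin along its axis (crossing
#' coordinate in `[0, threshold)`), i.e. prevalence drops below the target
#' in both SES groups at once. The likelihood is the eradicating fraction of
#' all `n_sim` simulated lines. The same simulated intercepts give the
#' percentile confidence interval for the intercept.
#'
#' Draw `i` of each wave is paired with draw `i` of every other wave; since
#' waves are estimated independently, any fixed pairing is distributionally
#' equivalent and this one keeps the pipeline deterministic given seeds.
#'
#' @param sim_points Long tibble with columns `sim`, `wave`, `p1`, `p0`:
#'   aligned prevalence draws for every wave (e.g. stacked
#'   [prevalence_pair()] clouds).
#' @param threshold Eradication cutoff on the prevalence scale
#'   (default 0.05), in (0, 1).
#' @param points Optional tibble of per-wave point estimates (`p1`, `p0`,
#'   optionally `year`) used to fit the headline [fit_trend()] line.
#' @param level Level of the intercept percentile interval (default 0.95).
#' @param stratum Optional label.
#' @return An object of class `trend_result`: list with `line` (the point
#'   estimate [trend_line], `NULL` when `points` is absent), `intercept_ci`,
#'   `eradication_likelihood`, `threshold`, `n_sim`, `n_excluded` (simulated
#'   wave-sets with constant `p1`, counted as non-eradicating), `n_none`
#'   (lines missing both axes), `per_sim` (tibble of simulated slope,
#'   intercept, crossing axis and coordinate), `stratum`.
#' @export
eradication_likelihood <- function(sim_points, threshold = 0.05, points = NULL,
                                   level = 0.95, stratum = NULL) {
  check_columns(sim_points, c("sim", "wave", "p1", "p0"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must be in (0, 1)", class = "ineqtrend_config_error")
  }
  P1 <- tidyr::pivot_wider(sim_points[c("sim", "wave", "p1")],
    names_from = "wave", values_from = "p1"
  )
  P0 <- tidyr::pivot_wider(sim_points[c("sim", "wave", "p0")],
    names_from = "wave", values_from = "p0"
  )
  sims <- P1$sim
  P1 <- as.matrix(P1[-1])
  P0 <- as.matrix(P0[-1])
  if (anyNA(P1) || anyNA(P0)) {
    rlang::abort("sim_points draws are not aligned across waves (missing sim x wave cells)")
  }
  n_sim <- nrow(P1)
  ols <- fit_trend_rows(P1, P0)
  n_excluded <- sum(!ols$ok)
  if (n_excluded > 0.01 * n_sim) {
    rlang::abort(
      sprintf(
        "%d of %d simulated wave-sets (%.1f%%) have constant high-SES prevalence; aborting",
        n_excluded, n_sim, 100 * n_excluded / n_sim
      ),
      class = "ineqtrend_degenerate_error"
    )
  }
  slope <- ols$slope
  intercept <- ols$intercept
  axis <- rep("none", n_sim)
  coord <- rep(NA_real_, n_sim)
  yfirst <- ols$ok & intercept >= 0
  xfirst <- ols$ok & intercept < 0 & slope > 0
  axis[yfirst] <- "y-axis"
  coord[yfirst] <- intercept[yfirst]
  axis[xfirst] <- "x-axis"
  coord[xfirst] <- -intercept[xfirst] / slope[xfirst]
  axis[!ols$ok] <- "excluded"
  eradicating <- !is.na(coord) & coord >= 0 & coord < threshold
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(intercept[ols$ok], c(alpha, 1 - alpha)))

  line <- if (!is.null(points)) fit_trend(points) else NULL
  if (!is.null(line) && (line$intercept < ci[1] || line$intercept > ci[2])) {
    rlang::inform(sprintf(
      "point-estimate intercept %.4f lies outside its percentile CI (%.4f, %.4f)",
      line$intercept, ci[1], ci[2]
    ))
  }
  structure(
    list(
      line = line,
      intercept_ci = ci,
      eradication_likelihood = sum(eradicating) / n_sim,
      threshold = threshold,
      n_sim = n_sim,
      n_excluded = n_excluded,
      n_none = sum(axis == "none"),
      per_sim = tibble::tibble(
        sim = sims, slope = slope, intercept = intercept,
        axis = axis, crossing = coord
      ),
      level = level,
      stratum = stratum
    ),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Eradication analysis", if (!is.null(x$stratum)) paste0(" [", x$stratum, "]"), "\n", sep = "")
  if (!is.null(x$line)) {
    cat(sprintf(
      "  line: slope %.3f, intercept %.3f (%d waves)\n",
      x$line$slope, x$line$intercept, x$line$n_points
    ))
  }
  cat(sprintf(
    "  intercept %.0f%% CI: (%.4f, %.4f)\n",
    100 * x$level, x$intercept_ci[1], x$intercept_ci[2]
  ))
  cat(sprintf(
    "  likelihood of eradication (<%.0f%% in both groups): %.1f%%\n",
    100 * x$threshold, 100 * x$eradication_likelihood
  ))
  if (x$n_excluded > 0 || x$n_none > 0) {
    cat(sprintf(
      "  %d degenerate simulations excluded; %d lines missed both axes\n",
      x$n_excluded, x$n_none
    ))
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.trend_result <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum %||% NA_character_,
    slope = if (!is.null(x$line)) x$line$slope else NA_real_,
    intercept = if (!is.null(x$line)) x$line$intercept else NA_real_,
    ci_lo = x$intercept_ci[1],
    ci_hi = x$intercept_ci[2],
    eradication_likelihood = x$eradication_likelihood
  )
}

#' @rdname tidy
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum %||% NA_character_,
    n_sim = x$n_sim,
    n_excluded = x$n_excluded,
    n_none = x$n_none,
    threshold = x$threshold,
    level = x$level
  )
}

#' Summarize trend results across strata
#'
#' One row per stratum (region by gender), on the percentage scale: the
#' estimated intercept (low-SES prevalence when high-SES prevalence is 0%),
#' its simulation-based confidence interval, and the likelihood of
#' eradication.
#'
#' @param results A list of `trend_result` objects (possibly empty). Each
#'   result's `stratum` is split on `"/"` into region and gender when it has
#'   that shape.
#' @return A tibble with columns `region`, `gender`, `intercept`, `ci_lo`,
#'   `ci_hi`, `eradication` (all prevalence quantities in percent), ordered
#'   as given.
#' @seealso [format_trend_table()] for a printable rendering.
#' @export
summarize_trends <- function(results) {
  empty <- tibble::tibble(
    region = character(), gender = character(),
    intercept = numeric(), ci_lo = numeric(), ci_hi = numeric(),
    eradication = numeric()
  )
  if (length(results) == 0) {
    return(empty)
  }
  purrr::map_dfr(results, function(r) {
    lab <- r$stratum %||% NA_character_
    parts <- strsplit(as.character(lab), "/", fixed = TRUE)[[1]]
    tibble::tibble(
      region = if (length(parts) >= 1) parts[1] else NA_character_,
      gender = if (length(parts) >= 2) parts[2] else NA_character_,
      intercept = 100 * (if (!is.null(r$line)) r$line$intercept else NA_real_),
      ci_lo = 100 * r$intercept_ci[1],
      ci_hi = 100 * r$intercept_ci[2],
      eradication = 100 * r$eradication_likelihood
    )
  })
}

#' Render a trend summary as an aligned text table
#'
#' Percentages are shown to one decimal; eradication likelihoods below 1%
#' are rendered as `"<1"`.
#'
#' @param summary A tibble from [summarize_trends()].
#' @return A character vector, one element per line.
#' @export
format_trend_table <- function(summary) {
  fmt_erad <- function(e) {
    ifelse(is.na(e), "NA", ifelse(e < 1, "<1", sprintf("%.0f", e)))
  }
  rows <- sprintf(
    "%-14s %-6s %6.1f  (%.1f, %.1f)  %s",
    summary$region, summary$gender, summary$intercept,
    summary$ci_lo, summary$ci_hi, fmt_erad(summary$eradication)
  )
  header <- sprintf(
    "%-14s %-6s %6s  %-12s  %s",
    "region", "gender", "int.%", "95% CI", "erad.%"
  )
  c(header, rows)
}
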