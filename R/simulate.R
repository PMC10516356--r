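#' Simulate coefficient vectors from a fitted stratum model
#'
#' Draws `n_sim` values of \eqn{(\beta_0, \beta_1)} from the bivariate normal
#' distribution with the fitted fixed effects as mean and their estimated
#' variance-covariance matrix as covariance. These draws carry the estimation
#' uncertainty of one stratum through every later step: prevalence pairs,
#' confidence regions, simulated trend lines and the eradication likelihood.
#'
#' @param fit A `ses_fit` from [fit_cluster_logit()] (or restored by
#'   [read_fits()]).
#' @param n_sim Number of draws (default 10000).
#' @param seed Optional integer seed; with a seed, repeated calls are
#'   bitwise identical.
#' @return A tibble of class `coef_draws` with columns `sim`, `beta0`,
#'   `beta1`, and attributes `stratum`, `seed`, `mean`, `vcov`.
#' @export
draw_coefficients <- function(fit, n_sim = 10000, seed = NULL) {
  if (!isTRUE(fit$converged)) {
    rlang::abort(paste0(
      "stratum ", fit$stratum %||% "<unnamed>",
      ": fit did not converge; refusing to simulate from it"
    ))
  }
  S <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    rlang::abort(
      paste0(
        "variance-covariance matrix is not positive semidefinite:\n",
        paste(utils::capture.output(print(S)), collapse = "\n")
      ),
      class = "ineqtrend_numerical_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n_sim, mu = c(fit$beta0, fit$beta1), Sigma = S)
  draws <- matrix(draws, ncol = 2) # mvrnorm drops dims when n_sim = 1
  out <- tibble::tibble(sim = seq_len(n_sim), beta0 = draws[, 1], beta1 = draws[, 2])
  structure(out,
    class = c("coef_draws", class(out)),
    stratum = fit$stratum, seed = seed,
    mean = c(beta0 = fit$beta0, beta1 = fit$beta1), vcov = S
  )
}

#' Prevalence at the extremes of the socioeconomic scale
#'
#' Maps logistic coefficients to the model-predicted outcome prevalence at
#' the bottom (`SES = 0`, the low-status extrapolation `P(0)`) and top
#' (`SES = 1`, `P(1)`) of the fractional-rank scale:
#' \eqn{P(0) = \mathrm{logit}^{-1}(\beta_0)} and
#' \eqn{P(1) = \mathrm{logit}^{-1}(\beta_0 + \beta_1)}. Vectorized.
#'
#' @param beta0,beta1 Numeric vectors of coefficients on the log-odds scale.
#' @return A tibble with columns `p1` and `p0`, one row per coefficient pair.
#' @examples
#' prevalence_at_extremes(-2, -1) # p1 = 1/(1 + e^3), p0 = 1/(1 + e^2)
#' @export
prevalence_at_extremes <- function(beta0, beta1) {
  tibble::tibble(
    p1 = stats::plogis(beta0 + beta1),
    p0 = stats::plogis(beta0)
  )
}

#' Prevalence pair with simulation cloud and percentile intervals
#'
#' Combines the point estimates of one stratum with its coefficient draws:
#' the point `(P(1), P(0))`, the cloud of simulated prevalence pairs, and
#' percentile confidence intervals for each coordinate (the 2.5th and 97.5th
#' percentiles of the simulated values at `level = 0.95`).
#'
#' @param fit A `ses_fit`.
#' @param draws A `coef_draws` for the same stratum (made if omitted, using
#'   `n_sim` and `seed`).
#' @param level Interval level (default 0.95).
#' @inheritParams draw_coefficients
#' @return An object of class `prevalence_pair`: a list with `stratum`,
#'   `p1`, `p0`, `cloud` (tibble `sim`, `p1`, `p0`), `ci_p1`, `ci_p0`,
#'   `level`.
#' @export
prevalence_pair <- function(fit, draws = NULL, level = 0.95, n_sim = 10000, seed = NULL) {
  if (is.null(draws)) draws <- draw_coefficients(fit, n_sim = n_sim, seed = seed)
  point <- prevalence_at_extremes(fit$beta0, fit$beta1)
  cloud <- prevalence_at_extremes(draws$beta0, draws$beta1)
  cloud <- tibble::tibble(sim = draws$sim, p1 = cloud$p1, p0 = cloud$p0)
  alpha <- (1 - level) / 2
  structure(
    list(
      stratum = fit$stratum,
      p1 = point$p1, p0 = point$p0,
      cloud = cloud,
      ci_p1 = unname(stats::quantile(cloud$p1, c(alpha, 1 - alpha))),
      ci_p0 = unname(stats::quantile(cloud$p0, c(alpha, 1 - alpha))),
      level = level
    ),
    class = "prevalence_pair"
  )
}

#' @export
print.prevalence_pair <- function(x, ...) {
  cat("Prevalence pair", if (!is.null(x$stratum)) paste0(" [", x$stratum, "]"), "\n", sep = "")
  cat(sprintf(
    "  P(1) = %.4f (%.0f%% CI %.4f, %.4f)\n  P(0) = %.4f (%.0f%% CI %.4f, %.4f)\n",
    x$p1, 100 * x$level, x$ci_p1[1], x$ci_p1[2],
    x$p0, 100 * x$level, x$ci_p0[1], x$ci_p0[2]
  ))
  invisible(x)
}

#' Confidence region for a prevalence point
#'
#' Builds the level-set ellipse of the bivariate normal fitted to the
#' coefficient draws (sample mean and covariance; squared radius from the
#' chi-square quantile with 2 degrees of freedom), discretizes its boundary,
#' and maps every boundary point through [prevalence_at_extremes()]. The
#' image of the ellipse under the inverse-logit map is the confidence region
#' for the point `(P(1), P(0))`; it is no longer an exact ellipse and bends
#' near the edges of the unit square, which is the intended behaviour for
#' prevalences near 0.
#'
#' @param draws A `coef_draws` (at least 100 draws).
#' @param level Region level (default 0.95).
#' @param n_points Number of boundary points (default 360).
#' @return A tibble of class `conf_region` with columns `p1`, `p0` tracing a
#'   closed curve (first point repeated last); attributes `stratum`, `level`,
#'   `degenerate`.
#' @export
confidence_region <- function(draws, level = 0.95, n_points = 360) {
  if (nrow(draws) < 100) {
    rlang::abort("confidence_region() needs at least 100 draws")
  }
  m <- c(mean(draws$beta0), mean(draws$beta1))
  S <- stats::cov(cbind(draws$beta0, draws$beta1))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  degenerate <- any(e$values < 1e-12 * max(e$values, 0) | e$values <= 0)
  if (degenerate) {
    rlang::warn("draw covariance is rank-deficient; confidence region collapses")
  }
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points + 1)
  circle <- rbind(cos(theta), sin(theta))
  bnd <- t(m + r * L %*% circle)
  out <- prevalence_at_extremes(bnd[, 1], bnd[, 2])
  structure(out,
    class = c("conf_region", class(out)),
    stratum = attr(draws, "stratum"), level = level, degenerate = degenerate
  )
}
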