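#' Cluster random-intercept logistic regression of outcome on SES
#'
#' Fits, for one stratum (typically a survey year by gender, possibly within
#' a region), the model
#' \deqn{\mathrm{logit}\, P(y_{ij} = 1) = \beta_0 + \beta_1\, s_{ij} + u_j,
#'   \qquad u_j \sim N(0, \sigma_u^2),}
#' where \eqn{s_{ij}} is the fractional-rank SES score of respondent \eqn{i}
#' in cluster \eqn{j}. The random intercept is integrated out by adaptive
#' Gauss--Hermite quadrature ([lme4::glmer()] with `nAGQ = nodes`; one node is
#' the Laplace approximation). Only the fixed effects \eqn{(\beta_0, \beta_1)}
#' and their variance-covariance matrix are carried into the downstream
#' simulation; \eqn{\sigma_u} is reported for diagnostics.
#'
#' Strata with a single cluster fall back to ordinary logistic regression
#' (with a message), since no between-cluster variance is identifiable. A
#' stratum in which only one outcome value occurs cannot be fitted and is
#' returned with `converged = FALSE`.
#'
#' @param data Tibble with columns `outcome` (0/1), `ses` (in (0, 1]) and
#'   `cluster`.
#' @param stratum Optional label (e.g. `"2015/boy"`) attached to the result.
#' @param nodes Number of adaptive Gauss--Hermite quadrature nodes
#'   (default 15).
#' @return An object of class `ses_fit`: a list with elements `beta0`,
#'   `beta1`, `vcov` (2x2 for the fixed effects), `sigma_u`, `n_obs`,
#'   `n_clusters`, `converged`, `stratum`, `nodes`, `engine` and `loglik`.
#' @seealso [marginal_loglik()] for the same likelihood evaluated directly,
#'   [draw_coefficients()] for the simulation step.
#' @export
fit_cluster_logit <- function(data, stratum = NULL, nodes = 15) {
  check_columns(data, c("outcome", "ses", "cluster"))
  data <- data[!is.na(data$outcome) & !is.na(data$ses) & !is.na(data$cluster), ]
  n_obs <- nrow(data)
  n_clusters <- length(unique(data$cluster))
  base <- list(
    beta0 = NA_real_, beta1 = NA_real_,
    vcov = matrix(NA_real_, 2, 2, dimnames = list(c("beta0", "beta1"), c("beta0", "beta1"))),
    sigma_u = NA_real_, n_obs = n_obs, n_clusters = n_clusters,
    converged = FALSE, stratum = stratum, nodes = nodes,
    engine = NA_character_, loglik = NA_real_
  )
  class(base) <- "ses_fit"

  if (n_obs == 0 || length(unique(data$outcome)) < 2) {
    rlang::warn(paste0(
      "stratum ", stratum %||% "<unnamed>",
      ": outcome does not vary (or no data); fit not attempted"
    ))
    return(base)
  }

  if (n_clusters < 2) {
    rlang::inform(paste0(
      "stratum ", stratum %||% "<unnamed>",
      ": fewer than 2 clusters; falling back to plain logistic regression"
    ))
    m <- stats::glm(outcome ~ ses, data = data, family = stats::binomial())
    base$beta0 <- unname(coef(m)[1])
    base$beta1 <- unname(coef(m)[2])
    v <- unname(stats::vcov(m))
    dimnames(v) <- dimnames(base$vcov)
    base$vcov <- v
    base$sigma_u <- 0
    base$converged <- m$converged && !any(is.na(coef(m)))
    base$engine <- "glm"
    base$loglik <- as.numeric(stats::logLik(m))
    return(base)
  }

  fit <- tryCatch(
    withCallingHandlers(
      lme4::glmer(outcome ~ ses + (1 | cluster),
        data = data, family = stats::binomial(), nAGQ = nodes,
        control = lme4::glmerControl(calc.derivs = TRUE)
      ),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    rlang::warn(paste0(
      "stratum ", stratum %||% "<unnamed>", ": fit failed (",
      conditionMessage(fit), ")"
    ))
    return(base)
  }
  fe <- lme4::fixef(fit)
  v <- as.matrix(stats::vcov(fit))
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(base$vcov)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  # a boundary (sigma_u -> 0) fit is a legitimate converged estimate
  boundary_only <- !is.null(conv_msgs) &&
    all(grepl("boundary \\(singular\\)", conv_msgs))
  base$beta0 <- unname(fe[1])
  base$beta1 <- unname(fe[2])
  base$vcov <- v
  base$sigma_u <- sqrt(unname(lme4::VarCorr(fit)$cluster[1, 1]))
  base$converged <- fit@optinfo$conv$opt == 0 &&
    (is.null(conv_msgs) || boundary_only)
  base$engine <- "glmer"
  base$loglik <- as.numeric(stats::logLik(fit))
  if (!base$converged) {
    rlang::warn(paste0(
      "stratum ", stratum %||% "<unnamed>", ": fit did not converge cleanly",
      if (!is.null(conv_msgs)) paste0(" (", paste(conv_msgs, collapse = "; "), ")")
    ))
  }
  base
}

#' @export
print.ses_fit <- function(x, ...) {
  cat("Cluster random-intercept logistic fit",
    if (!is.null(x$stratum)) paste0(" [", x$stratum, "]"), "\n",
    sep = ""
  )
  cat(sprintf(
    "  beta0 = %.4f, beta1 = %.4f, sigma_u = %.4f\n",
    x$beta0, x$beta1, x$sigma_u
  ))
  cat(sprintf(
    "  n_obs = %d, n_clusters = %d, engine = %s, converged = %s\n",
    x$n_obs, x$n_clusters, x$engine, x$converged
  ))
  invisible(x)
}

#' Tidy a cluster-logistic fit
#'
#' @param x A `ses_fit` from [fit_cluster_logit()].
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.ses_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "ses"),
    estimate = c(x$beta0, x$beta1),
    std.error = sqrt(diag(x$vcov))
  )
}

#' One-row summary of a cluster-logistic fit
#'
#' @inheritParams tidy.ses_fit
#' @return A one-row tibble with fit diagnostics.
#' @export
glance.ses_fit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum %||% NA_character_,
    sigma_u = x$sigma_u,
    n_obs = x$n_obs,
    n_clusters = x$n_clusters,
    logLik = x$loglik,
    converged = x$converged,
    engine = x$engine
  )
}

#' Generic tidiers
#'
#' Broom-style generics; methods are provided for the package's fitted
#' objects.
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

# ---- marginal likelihood (independent quadrature route) ----------------------

# Gauss-Hermite nodes and weights (physicists' convention, weight e^{-z^2})
# by Golub-Welsch: eigen-decomposition of the symmetric tridiagonal Jacobi
# matrix with off-diagonals sqrt(k/2); weights are sqrt(pi) times the squared
# first components of the eigenvectors.
gh_rule <- function(n) {
  if (n == 1) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates, at user-supplied parameter values, the same marginal likelihood
#' that [fit_cluster_logit()] maximizes: for each cluster the random
#' intercept is integrated out by adaptive Gauss--Hermite quadrature centred
#' and scaled at the mode of the integrand (found by Newton iteration). With
#' `sigma_u = 0` the model collapses to ordinary logistic regression and the
#' exact Bernoulli log-likelihood is returned. Exposed so that the fitted
#' optimum can be checked against independent numerical integration and
#' probed for local optimality.
#'
#' @param data Tibble with columns `outcome`, `ses`, `cluster`.
#' @param beta0,beta1 Fixed intercept and SES slope on the log-odds scale.
#' @param sigma_u Random-intercept standard deviation, `>= 0`.
#' @param nodes Number of quadrature nodes (default 15; 1 gives the Laplace
#'   approximation).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(data, beta0, beta1, sigma_u, nodes = 15) {
  check_columns(data, c("outcome", "ses", "cluster"))
  if (!is.finite(sigma_u) || sigma_u < 0) {
    rlang::abort("sigma_u must be finite and >= 0", class = "ineqtrend_domain_error")
  }
  eta0 <- beta0 + beta1 * data$ses
  y <- data$outcome
  if (sigma_u == 0) {
    return(sum(stats::dbinom(y, 1, stats::plogis(eta0), log = TRUE)))
  }
  rule <- gh_rule(nodes)
  cl <- split(seq_len(nrow(data)), data$cluster)
  total <- 0
  for (idx in cl) {
    yi <- y[idx]
    ei <- eta0[idx]
    # log-integrand h(u) = sum Bernoulli loglik(u) + log Normal(u; 0, sigma^2)
    h <- function(u) {
      sum(stats::dbinom(yi, 1, stats::plogis(ei + u), log = TRUE)) -
        u^2 / (2 * sigma_u^2) - log(sigma_u) - 0.5 * log(2 * pi)
    }
    # Newton search for the mode of h
    u <- 0
    for (it in 1:100) {
      p <- stats::plogis(ei + u)
      g <- sum(yi - p) - u / sigma_u^2
      hess <- -sum(p * (1 - p)) - 1 / sigma_u^2
      step <- g / hess
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    p <- stats::plogis(ei + u)
    tau <- 1 / sqrt(sum(p * (1 - p)) + 1 / sigma_u^2)
    z <- u + sqrt(2) * tau * rule$nodes
    hv <- vapply(z, h, numeric(1))
    total <- total + log(sqrt(2) * tau) +
      log_sum_exp(log(rule$weights) + rule$nodes^2 + hv)
  }
  total
}

# ---- JSON archive of per-stratum fits ---------------------------------------

#' Archive and restore per-stratum fits as JSON
#'
#' Step-1 outputs (fixed effects, their variance-covariance matrix and fit
#' diagnostics per stratum) can be saved to JSON and fed back into the
#' simulation and trend steps without refitting.
#'
#' @param fits A list of `ses_fit` objects.
#' @param path JSON file path.
#' @return `write_fits()` returns `path` invisibly; `read_fits()` returns a
#'   list of `ses_fit` objects.
#' @export
write_fits <- function(fits, path) {
  if (inherits(fits, "ses_fit")) fits <- list(fits)
  payload <- lapply(fits, function(f) {
    list(
      stratum = f$stratum, beta0 = f$beta0, beta1 = f$beta1,
      vcov = as.vector(f$vcov), sigma_u = f$sigma_u,
      n_obs = f$n_obs, n_clusters = f$n_clusters,
      converged = f$converged, nodes = f$nodes,
      engine = f$engine, loglik = f$loglik
    )
  })
  # digits = I(17): significant digits, enough for lossless double round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    f <- list(
      beta0 = as.numeric(p$beta0), beta1 = as.numeric(p$beta1),
      vcov = matrix(as.numeric(unlist(p$vcov)), 2, 2,
        dimnames = list(c("beta0", "beta1"), c("beta0", "beta1"))
      ),
      sigma_u = as.numeric(p$sigma_u), n_obs = as.integer(p$n_obs),
      n_clusters = as.integer(p$n_clusters),
      converged = isTRUE(p$converged), stratum = p$stratum,
      nodes = as.integer(p$nodes), engine = as.character(p$engine),
      loglik = as.numeric(p$loglik)
    )
    class(f) <- "ses_fit"
    f
  })
}
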