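# Fixture builders and independent oracles used across test files.

toy_survey <- function() {
  tibble::tibble(
    respondent_id = sprintf("r%d", 1:5),
    country = c("A", "A", "A", "B", "B"),
    cluster = c("A-1", "A-1", "A-2", "B-1", "B-1"),
    year = c(2003L, 2003L, 2007L, 2003L, 2007L),
    gender = c("boy", "girl", "boy", "girl", "boy"),
    outcome = c(0L, 1L, 0L, 1L, 0L),
    edu_mother = c(1L, 3L, NA, 5L, 2L),
    edu_father = c(2L, NA, 4L, 1L, 2L)
  )
}

# Brute-force fractional rank: explicit positions after a stable sort, mean of
# the positions each category occupies, divided by n. Independent of ses_rank().
rank_oracle <- function(edu) {
  n <- length(edu)
  pos <- numeric(n)
  pos[order(edu)] <- seq_len(n)
  out <- numeric(n)
  for (cat in unique(edu)) {
    idx <- which(edu == cat)
    out[idx] <- mean(pos[idx])
  }
  out / n
}

# Clustered binary data from known truth, for parameter-recovery tests.
gen_cluster_data <- function(n_clusters, per_cluster, beta0, beta1, sigma_u, seed) {
  set.seed(seed)
  n <- n_clusters * per_cluster
  cl <- rep(seq_len(n_clusters), each = per_cluster)
  u <- rnorm(n_clusters, 0, sigma_u)
  ses <- runif(n)
  tibble::tibble(
    outcome = rbinom(n, 1, plogis(beta0 + beta1 * ses + u[cl])),
    ses = ses,
    cluster = sprintf("c%04d", cl)
  )
}

# Trapezoid-grid integration of the marginal likelihood: the independent
# oracle for the adaptive-quadrature route. Fine grid over +/- width*sigma.
grid_loglik <- function(data, beta0, beta1, sigma_u, width = 10, n_grid = 40001) {
  eta0 <- beta0 + beta1 * data$ses
  total <- 0
  for (idx in split(seq_len(nrow(data)), data$cluster)) {
    u <- seq(-width * sigma_u, width * sigma_u, length.out = n_grid)
    h <- vapply(u, function(uu) {
      sum(dbinom(data$outcome[idx], 1, plogis(eta0[idx] + uu), log = TRUE)) +
        dnorm(uu, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(h)
    v <- exp(h - m)
    du <- u[2] - u[1]
    total <- total + m + log(sum((v[-1] + v[-length(v)]) / 2) * du)
  }
  total
}

# A ses_fit built directly from coefficients, for simulation tests that do
# not need a real model fit behind them.
make_fit <- function(beta0, beta1, vcov = diag(c(0.01, 0.02)), sigma_u = 0.3,
                     stratum = "test", converged = TRUE) {
  structure(
    list(
      beta0 = beta0, beta1 = beta1,
      vcov = matrix(as.numeric(vcov), 2, 2,
        dimnames = list(c("beta0", "beta1"), c("beta0", "beta1"))
      ),
      sigma_u = sigma_u, n_obs = NA_integer_, n_clusters = NA_integer_,
      converged = converged, stratum = stratum, nodes = 15L,
      engine = "synthetic", loglik = NA_real_
    ),
    class = "ses_fit"
  )
}

# Aligned simulation draws in which every simulated wave-set lies exactly on
# the line p0 = intercept + slope * p1 (noise-free draw clouds).
line_draws <- function(slope, intercept, p1_waves, n_sim) {
  tidyr::expand_grid(sim = seq_len(n_sim), wave = seq_along(p1_waves)) |>
    dplyr::mutate(
      p1 = p1_waves[wave],
      p0 = intercept + slope * .data$p1
    )
}

# Even-odd point-in-polygon test for confidence-region containment checks.
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
      px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
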