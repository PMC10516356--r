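test_that("adaptive quadrature matches grid integration on tiny clustered data", {
  d <- gen_cluster_data(3, 4, beta0 = -0.5, beta1 = -1, sigma_u = 0.6, seed = 101)
  params <- list(
    c(-0.5, -1.0, 0.6),
    c(0.2, 0.5, 0.3),
    c(-1.5, 2.0, 1.0),
    c(0.0, 0.0, 0.2)
  )
  for (p in params) {
    expect_equal(
      marginal_loglik(d, p[1], p[2], p[3], nodes = 15),
      grid_loglik(d, p[1], p[2], p[3]),
      tolerance = 1e-6
    )
  }
})

test_that("sigma_u = 0 collapses to the plain logistic log-likelihood exactly", {
  d <- gen_cluster_data(3, 5, beta0 = 0.3, beta1 = -0.8, sigma_u = 0.4, seed = 7)
  expect_identical(
    marginal_loglik(d, 0.3, -0.8, 0),
    sum(dbinom(d$outcome, 1, plogis(0.3 - 0.8 * d$ses), log = TRUE))
  )
  expect_error(marginal_loglik(d, 0, 0, -0.1), class = "ineqtrend_domain_error")
})

test_that("the fitted optimum agrees with the independent likelihood and is locally optimal", {
  d <- gen_cluster_data(30, 15, beta0 = -1, beta1 = -1.5, sigma_u = 0.5, seed = 42)
  fit <- fit_cluster_logit(d, stratum = "opt", nodes = 15)
  expect_true(fit$converged)
  ll_hat <- marginal_loglik(d, fit$beta0, fit$beta1, fit$sigma_u, nodes = 15)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-4)
  for (delta in list(c(0.05, 0, 0), c(0, 0.05, 0), c(0, 0, 0.05), c(-0.04, 0.04, 0))) {
    expect_lt(
      marginal_loglik(
        d, fit$beta0 + delta[1], fit$beta1 + delta[2],
        max(fit$sigma_u + delta[3], 1e-8),
        nodes = 15
      ),
      ll_hat
    )
  }
})

test_that("parameter recovery on moderately sized synthetic data", {
  d <- gen_cluster_data(100, 100, beta0 = -1, beta1 = -1.5, sigma_u = 0.5, seed = 9)
  fit <- fit_cluster_logit(d, nodes = 7)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta0 - (-1)) / se[1], 3)
  expect_lt(abs(fit$beta1 - (-1.5)) / se[2], 3)
  expect_equal(fit$sigma_u, 0.5, tolerance = 0.3)
  expect_equal(fit$n_obs, 10000L)
  expect_equal(fit$n_clusters, 100L)
})

test_that("shifting the SES score moves the intercept by -beta1*c and keeps the slope", {
  d <- gen_cluster_data(40, 25, beta0 = -1, beta1 = -1.2, sigma_u = 0.4, seed = 15)
  f1 <- fit_cluster_logit(d, nodes = 7)
  d2 <- dplyr::mutate(d, ses = ses + 0.5)
  f2 <- fit_cluster_logit(d2, nodes = 7)
  expect_equal(f2$beta1, f1$beta1, tolerance = 5e-3)
  expect_equal(f2$beta0, f1$beta0 - f1$beta1 * 0.5, tolerance = 5e-3)
})

test_that("single-cluster strata fall back to ordinary logistic regression", {
  d <- gen_cluster_data(1, 60, beta0 = 0, beta1 = -1, sigma_u = 0, seed = 3)
  expect_message(fit <- fit_cluster_logit(d, stratum = "one"), "plain logistic")
  ref <- glm(outcome ~ ses, data = d, family = binomial())
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(fit$sigma_u, 0)
  expect_equal(fit$engine, "glm")
})

test_that("a stratum whose outcome does not vary is flagged, not fitted", {
  d <- gen_cluster_data(3, 5, 0, 0, 0.1, seed = 2)
  d$outcome <- 1L
  expect_warning(fit <- fit_cluster_logit(d, stratum = "flat"), "does not vary")
  expect_false(fit$converged)
  expect_true(is.na(fit$beta0))
})

test_that("fits archive to JSON and restore identically", {
  d <- gen_cluster_data(20, 10, -1, -1, 0.3, seed = 8)
  fit <- fit_cluster_logit(d, stratum = "arch", nodes = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_fits(list(fit), path)
  back <- read_fits(path)[[1]]
  expect_equal(back$beta0, fit$beta0)
  expect_equal(back$beta1, fit$beta1)
  expect_equal(back$vcov, fit$vcov)
  expect_equal(back$sigma_u, fit$sigma_u)
  expect_equal(back$stratum, "arch")
  expect_true(back$converged)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- gen_cluster_data(15, 10, -1, -1, 0.3, seed = 88)
  fit <- fit_cluster_logit(d, stratum = "t", nodes = 5)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "ses"))
  expect_equal(td$estimate, c(fit$beta0, fit$beta1))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 15L)
  expect_true(gl$converged)
})
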