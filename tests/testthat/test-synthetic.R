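small_scenario <- function(...) {
  new_scenario(
    n_countries = 3, clusters_per_country = 8, respondents_per_cluster = 15,
    ...
  )
}

test_that("scenario_from_line inverts the prevalence geometry exactly", {
  sc <- scenario_from_line(0.72, 0.094, c(0.22, 0.19, 0.17, 0.10),
    n_countries = 2, clusters_per_country = 2, respondents_per_cluster = 2
  )
  tp <- true_prevalences(sc)
  expect_equal(tp$p1, c(0.22, 0.19, 0.17, 0.10), tolerance = 1e-12)
  expect_equal(tp$p0, 0.094 + 0.72 * tp$p1, tolerance = 1e-12)
  expect_equal(sc$waves, c(2003L, 2007L, 2011L, 2015L))

  eq <- scenario_from_line(1, 0, c(0.3, 0.2, 0.1),
    n_countries = 2, clusters_per_country = 2, respondents_per_cluster = 2
  )
  expect_equal(eq$true_beta1, rep(0, 3))

  set.seed(9)
  for (i in 1:10) {
    s <- runif(1, 0.3, 1.2)
    b <- runif(1, -0.05, 0.15)
    p1 <- sort(runif(3, 0.05, 0.5), decreasing = TRUE)
    if (any(b + s * p1 <= 0 | b + s * p1 >= 1)) next
    sci <- scenario_from_line(s, b, p1,
      n_countries = 2,
      clusters_per_country = 2, respondents_per_cluster = 2
    )
    tpi <- true_prevalences(sci)
    expect_equal(tpi$p0, b + s * tpi$p1, tolerance = 1e-12)
  }

  expect_error(
    scenario_from_line(1, 0.9, c(0.5, 0.3)),
    class = "ineqtrend_domain_error"
  )
})

test_that("micro-data generation is reproducible and schema-complete", {
  sc <- small_scenario(seed = 12)
  d1 <- generate_microdata(sc)
  d2 <- generate_microdata(sc)
  expect_identical(d1, d2)
  expect_equal(
    names(d1),
    c(
      "respondent_id", "country", "cluster", "year", "gender",
      "outcome", "edu_mother", "edu_father"
    )
  )
  expect_equal(
    nrow(d1),
    3 * 4 * 8 * 15
  )
  expect_true(all(d1$outcome %in% 0:1))
  # the resolved household category is the generating (mother's) category
  expect_equal(
    resolve_household_education(d1$edu_mother, d1$edu_father),
    d1$edu_mother
  )
  # clusters are fresh per wave
  expect_equal(
    nrow(unique(d1[c("cluster")])),
    3 * 4 * 8
  )
})

test_that("the null scenario produces 50% prevalence within binomial tolerance", {
  sc <- small_scenario(
    true_beta0 = 0, true_beta1 = 0, sigma_u = 0,
    waves = c(2003L, 2007L), seed = 4
  )
  d <- generate_microdata(sc)
  n <- nrow(d)
  expect_equal(mean(d$outcome), 0.5, tolerance = 4 * sqrt(0.25 / n))
})

test_that("cluster-level outcome variance increases with sigma_u", {
  cluster_var <- function(sigma_u, seed) {
    sc <- small_scenario(
      sigma_u = sigma_u, seed = seed, waves = 2003L,
      true_beta0 = 0, true_beta1 = 0
    )
    d <- generate_microdata(sc)
    var(tapply(d$outcome, d$cluster, mean))
  }
  vs <- vapply(1:4, function(s) cluster_var(0, s), numeric(1))
  vb <- vapply(1:4, function(s) cluster_var(1.5, s), numeric(1))
  expect_gt(mean(vb), mean(vs))
})

test_that("scenarios round-trip through YAML", {
  sc <- small_scenario(seed = 31, sigma_u = 0.7, true_beta0 = c(-1, -1.2, -1.4, -1.6))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$ses_category_probs, sc$ses_category_probs, tolerance = 1e-12)
  expect_equal(back$true_beta0, sc$true_beta0)
  expect_equal(back$sigma_u, sc$sigma_u)
  expect_identical(generate_microdata(back), generate_microdata(sc))
})

test_that("scenario validation rejects malformed category distributions", {
  expect_error(
    new_scenario(n_countries = 2, ses_category_probs = matrix(0.5, 1, 5)),
    class = "ineqtrend_config_error"
  )
  expect_error(
    new_scenario(n_countries = 1, ses_category_probs = matrix(c(0.5, 0.2, 0.1, 0.1, 0.2), 1)),
    class = "ineqtrend_config_error"
  )
})

test_that("fitting generated data recovers the generating coefficients", {
  sc <- new_scenario(
    n_countries = 4, clusters_per_country = 25, respondents_per_cluster = 30,
    waves = 2003L, true_beta0 = -1, true_beta1 = -1.5, sigma_u = 0.5, seed = 55
  )
  d <- generate_microdata(sc)
  scored <- ses_rank(exclude_incomplete(d))
  fit <- fit_cluster_logit(scored, nodes = 7)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta0 - (-1)) / se[1], 3)
  expect_lt(abs(fit$beta1 - (-1.5)) / se[2], 3)
  expect_equal(fit$sigma_u, 0.5, tolerance = 0.35)
})
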