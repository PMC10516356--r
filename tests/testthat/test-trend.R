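test_that("the trend line matches closed-form least squares", {
  ident <- fit_trend(tibble::tibble(p1 = c(0.1, 0.2, 0.3), p0 = c(0.1, 0.2, 0.3)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  # hand-computed normal-equation solution for a 4-wave set
  pts <- tibble::tibble(
    p1 = c(0.10, 0.20, 0.25, 0.30),
    p0 = c(0.15, 0.22, 0.24, 0.31)
  )
  line <- fit_trend(pts)
  expect_equal(line$slope, 0.0165 / 0.021875, tolerance = 1e-12)
  expect_equal(line$intercept, 0.23 - (0.0165 / 0.021875) * 0.2125, tolerance = 1e-12)
  expect_equal(line$n_points, 4L)

  ref <- lm(p0 ~ p1, data = pts) # independent route
  expect_equal(line$intercept, unname(coef(ref)[1]))
  expect_equal(line$slope, unname(coef(ref)[2]))
})

test_that("two waves are interpolated exactly and affine shifts move only the intercept", {
  two <- fit_trend(tibble::tibble(p1 = c(0.1, 0.3), p0 = c(0.12, 0.28)))
  expect_equal(two$intercept + two$slope * c(0.1, 0.3), c(0.12, 0.28))

  pts <- tibble::tibble(p1 = c(0.1, 0.2, 0.25, 0.3), p0 = c(0.15, 0.22, 0.24, 0.31))
  base <- fit_trend(pts)
  shifted <- fit_trend(dplyr::mutate(pts, p0 = p0 + 0.07))
  expect_equal(shifted$slope, base$slope)
  expect_equal(shifted$intercept, base$intercept + 0.07)

  scaled <- fit_trend(dplyr::mutate(pts, p0 = p0 * 0.5, p1 = p1 * 0.5))
  expect_equal(scaled$slope, base$slope)
  expect_equal(scaled$intercept, base$intercept * 0.5)
})

test_that("a vertical trend is refused with the waves named", {
  pts <- tibble::tibble(year = c(2003, 2007), p1 = c(0.2, 0.2), p0 = c(0.1, 0.3))
  expect_error(fit_trend(pts), "2003, 2007", class = "ineqtrend_degenerate_error")
  expect_error(fit_trend(pts[1, ]), class = "ineqtrend_input_error")
})

test_that("axis crossings follow the direction of declining prevalence", {
  y <- axis_intersection(list(slope = 0.72, intercept = 0.094))
  expect_equal(y, tibble::tibble(x = 0, y = 0.094, axis = "y-axis"))

  x <- axis_intersection(list(slope = 1, intercept = -0.02))
  expect_equal(x, tibble::tibble(x = 0.02, y = 0, axis = "x-axis"))

  origin <- axis_intersection(list(slope = 1, intercept = 0))
  expect_equal(origin$axis, "y-axis")
  expect_equal(c(origin$x, origin$y), c(0, 0))

  none <- axis_intersection(list(slope = -0.5, intercept = -0.1))
  expect_equal(none$axis, "none")
  expect_true(is.na(none$x) && is.na(none$y))
})

test_that("noise-free draw clouds give eradication likelihood 0, 1 and exact mixtures", {
  p1w <- c(0.22, 0.19, 0.17, 0.10)

  all_out <- eradication_likelihood(line_draws(0.72, 0.094, p1w, 400))
  expect_equal(all_out$eradication_likelihood, 0)
  expect_equal(all_out$intercept_ci, c(0.094, 0.094))

  all_in <- eradication_likelihood(line_draws(1, 0.02, p1w, 400))
  expect_equal(all_in$eradication_likelihood, 1)

  # x-axis route: negative intercept, crossing inside the zone
  x_in <- eradication_likelihood(line_draws(1, -0.02, p1w, 400))
  expect_equal(x_in$eradication_likelihood, 1)
  expect_true(all(x_in$per_sim$axis == "x-axis"))

  mix <- dplyr::bind_rows(
    line_draws(1, 0.02, p1w, 200),
    dplyr::mutate(line_draws(1, 0.10, p1w, 200), sim = sim + 200)
  )
  expect_equal(eradication_likelihood(mix)$eradication_likelihood, 0.5)
})

test_that("eradication likelihood is monotone non-decreasing in the threshold", {
  set.seed(77)
  n_sim <- 300
  p1w <- c(0.22, 0.19, 0.17, 0.10)
  sim <- line_draws(0.8, 0.03, p1w, n_sim)
  sim$p0 <- sim$p0 + rnorm(nrow(sim), 0, 0.02)
  sim$p1 <- pmin(pmax(sim$p1 + rnorm(nrow(sim), 0, 0.02), 1e-6), 1 - 1e-6)
  liks <- vapply(
    c(0.01, 0.03, 0.05, 0.1, 0.2, 0.5),
    function(thr) eradication_likelihood(sim, threshold = thr)$eradication_likelihood,
    numeric(1)
  )
  expect_true(all(diff(liks) >= 0))
  expect_error(eradication_likelihood(sim, threshold = 0), class = "ineqtrend_config_error")
})

test_that("degenerate simulated wave-sets are excluded, counted and capped", {
  p1w <- c(0.22, 0.19, 0.17, 0.10)
  sim <- line_draws(1, 0.02, p1w, 400)
  # one flat simulation (0.25% of draws): excluded, counted non-eradicating
  sim$p1[sim$sim == 1] <- 0.2
  res <- eradication_likelihood(sim)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$eradication_likelihood, 399 / 400)
  expect_equal(res$per_sim$axis[1], "excluded")

  # more than 1% flat simulations aborts with diagnostics
  bad <- line_draws(1, 0.02, p1w, 100)
  bad$p1[bad$sim <= 2] <- 0.2
  expect_error(eradication_likelihood(bad), class = "ineqtrend_degenerate_error")
})

test_that("intercept CI is the percentile interval of the simulated intercepts", {
  set.seed(5)
  p1w <- c(0.2, 0.15, 0.1)
  sim <- line_draws(0.8, 0.05, p1w, 500)
  sim$p0 <- sim$p0 + rnorm(nrow(sim), 0, 0.01)
  res <- eradication_likelihood(sim,
    points = tibble::tibble(p1 = p1w, p0 = 0.05 + 0.8 * p1w)
  )
  ok <- res$per_sim$axis != "excluded"
  expect_equal(
    res$intercept_ci,
    unname(quantile(res$per_sim$intercept[ok], c(0.025, 0.975)))
  )
  expect_equal(res$line$intercept, 0.05, tolerance = 1e-12)
})

test_that("trend summaries render region, gender and the <1 percent convention", {
  res <- eradication_likelihood(
    line_draws(0.72, 0.094, c(0.22, 0.19, 0.17, 0.10), 300),
    points = tibble::tibble(
      p1 = c(0.22, 0.19, 0.17, 0.10),
      p0 = 0.094 + 0.72 * c(0.22, 0.19, 0.17, 0.10)
    ),
    stratum = "All countries/boy"
  )
  res$intercept_ci <- c(0.061, 0.127) # from a wider simulation, for rendering
  res$eradication_likelihood <- 0.004
  tbl <- summarize_trends(list(res))
  expect_equal(tbl$region, "All countries")
  expect_equal(tbl$gender, "boy")
  expect_equal(tbl$intercept, 9.4, tolerance = 1e-10)
  expect_equal(c(tbl$ci_lo, tbl$ci_hi), c(6.1, 12.7))
  expect_equal(tbl$eradication, 0.4)
  txt <- format_trend_table(tbl)
  expect_match(txt[2], "9.4")
  expect_match(txt[2], "<1")

  empty <- summarize_trends(list())
  expect_equal(nrow(empty), 0)
  expect_equal(
    names(empty),
    c("region", "gender", "intercept", "ci_lo", "ci_hi", "eradication")
  )

  two <- summarize_trends(list(res, res))
  expect_equal(nrow(two), 2)
})
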