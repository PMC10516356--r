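#' Define a synthetic survey scenario with known ground truth
#'
#' A scenario describes a repeated cross-sectional school survey: several
#' countries, each sampled in every wave through fresh clusters
#' (classes/schools) of respondents, an ordinal parental-education
#' distribution that differs between countries, and a per-wave logistic
#' gradient of the binary outcome on the fractional-rank SES score with
#' cluster-level random variation. Because the generating model applies its
#' SES effect to the same ranked score the analysis pipeline computes, the
#' scenario's true per-wave prevalence pair is available in closed form
#' ([true_prevalences()]) and every pipeline stage can be validated against
#' it.
#'
#' @param n_countries Number of countries (default 10).
#' @param waves Integer survey years (default `c(2003, 2007, 2011, 2015)`).
#' @param clusters_per_country Clusters sampled per country per wave
#'   (default 40).
#' @param respondents_per_cluster Respondents per cluster (default 50). The
#'   defaults give about 20,000 respondents per wave, a scale at which the
#'   per-wave prevalence extremes are estimated precisely enough for the
#'   trend step to be informative.
#' @param n_categories Ordinal education categories (default 5, matching the
#'   common five-level completed-schooling scale).
#' @param ses_category_probs Optional `n_countries x n_categories` matrix of
#'   per-country category probabilities (rows sum to 1). When `NULL`,
#'   country-specific distributions are drawn once from a symmetric
#'   Dirichlet(2) using `seed`, so countries genuinely differ and the
#'   per-country ranking is exercised.
#' @param true_beta0,true_beta1 Per-wave fixed intercept and SES slope on
#'   the log-odds scale (length 1 or `length(waves)`).
#' @param sigma_u Cluster random-intercept standard deviation (default 0.5).
#' @param gender_split Probability a respondent is a boy (default 0.5).
#' @param seed Integer seed controlling both the Dirichlet category
#'   distributions and [generate_microdata()].
#' @return An object of class `scenario` (a list of the above, validated).
#' @export
new_scenario <- function(n_countries = 10,
                         waves = c(2003L, 2007L, 2011L, 2015L),
                         clusters_per_country = 40,
                         respondents_per_cluster = 50,
                         n_categories = 5,
                         ses_category_probs = NULL,
                         true_beta0 = -1,
                         true_beta1 = -1.5,
                         sigma_u = 0.5,
                         gender_split = 0.5,
                         seed = 1) {
  n_waves <- length(waves)
  stopifnot(
    n_countries >= 1, n_waves >= 1, clusters_per_country >= 1,
    respondents_per_cluster >= 1, n_categories >= 2,
    sigma_u >= 0, gender_split >= 0, gender_split <= 1
  )
  true_beta0 <- rep_len(true_beta0, n_waves)
  true_beta1 <- rep_len(true_beta1, n_waves)
  if (is.null(ses_category_probs)) {
    # country-specific category mixes, fixed by the scenario seed
    old <- .Random.seed_if_exists()
    set.seed(substream_seed(seed, "ses_category_probs"))
    g <- matrix(stats::rgamma(n_countries * n_categories, shape = 2), n_countries)
    ses_category_probs <- g / rowSums(g)
    .Random.seed_restore(old)
  }
  ses_category_probs <- as.matrix(ses_category_probs)
  if (nrow(ses_category_probs) != n_countries ||
    ncol(ses_category_probs) != n_categories) {
    rlang::abort("ses_category_probs must be n_countries x n_categories",
      class = "ineqtrend_config_error"
    )
  }
  if (any(ses_category_probs < 0) ||
    any(abs(rowSums(ses_category_probs) - 1) > 1e-8)) {
    rlang::abort("ses_category_probs rows must be nonnegative and sum to 1",
      class = "ineqtrend_config_error"
    )
  }
  structure(
    list(
      n_countries = as.integer(n_countries), waves = as.integer(waves),
      clusters_per_country = as.integer(clusters_per_country),
      respondents_per_cluster = as.integer(respondents_per_cluster),
      n_categories = as.integer(n_categories),
      ses_category_probs = ses_category_probs,
      true_beta0 = true_beta0, true_beta1 = true_beta1,
      sigma_u = sigma_u, gender_split = gender_split,
      seed = as.integer(seed)
    ),
    class = "scenario"
  )
}

.Random.seed_if_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic survey scenario: %d countries x %d waves x %d clusters x %d respondents\n",
    x$n_countries, length(x$waves), x$clusters_per_country, x$respondents_per_cluster
  ))
  tp <- true_prevalences(x)
  cat(sprintf(
    "  wave %d: beta0 = %.3f, beta1 = %.3f  ->  P(1) = %.3f, P(0) = %.3f\n",
    x$waves, x$true_beta0, x$true_beta1, tp$p1, tp$p0
  ), sep = "")
  cat(sprintf("  sigma_u = %.3f, seed = %d\n", x$sigma_u, x$seed))
  invisible(x)
}

#' True per-wave prevalence pairs implied by a scenario
#'
#' @param scenario A [new_scenario()].
#' @return A tibble with columns `wave`, `p1`, `p0` computed in closed form
#'   from the true coefficients.
#' @export
true_prevalences <- function(scenario) {
  pe <- prevalence_at_extremes(scenario$true_beta0, scenario$true_beta1)
  tibble::tibble(wave = scenario$waves, p1 = pe$p1, p0 = pe$p0)
}

#' Build a scenario whose true prevalences trace a given trend line
#'
#' Inverts a prevalence-space line `p0 = intercept + slope * p1` into
#' per-wave logistic coefficients: with the implied `p0` per wave,
#' `true_beta0 = logit(p0)` and `true_beta1 = logit(p1) - logit(p0)`, so
#' [true_prevalences()] returns exactly the intended pairs. Used for
#' end-to-end recovery tests in which the whole pipeline should rediscover
#' the line.
#'
#' @param slope,intercept Line in prevalence space.
#' @param p1_per_wave High-SES prevalence per wave, each in (0, 1).
#' @param ... Remaining scenario fields passed to [new_scenario()].
#' @return A `scenario` whose `waves` default to consecutive quadrennial
#'   years matching `length(p1_per_wave)` unless supplied in `...`.
#' @examples
#' sc <- scenario_from_line(0.72, 0.094, c(0.22, 0.19, 0.17, 0.10))
#' true_prevalences(sc)
#' @export
scenario_from_line <- function(slope, intercept, p1_per_wave, ...) {
  p0 <- intercept + slope * p1_per_wave
  if (any(p1_per_wave <= 0 | p1_per_wave >= 1) || any(p0 <= 0 | p0 >= 1)) {
    rlang::abort(
      "implied prevalences must lie strictly inside (0, 1)",
      class = "ineqtrend_domain_error"
    )
  }
  beta0 <- stats::qlogis(p0)
  beta1 <- stats::qlogis(p1_per_wave) - stats::qlogis(p0)
  dots <- list(...)
  if (is.null(dots$waves)) {
    dots$waves <- seq(2003L, by = 4L, length.out = length(p1_per_wave))
  }
  do.call(new_scenario, c(
    list(true_beta0 = beta0, true_beta1 = beta1),
    dots
  ))
}

#' Generate individual-level micro-data from a scenario
#'
#' For every country and wave, draws fresh clusters with normal random
#' intercepts, samples each respondent's parental-education category from
#' the country's distribution, scores SES by the same per-country pooled
#' fractional rank used by [ses_rank()], and draws the binary outcome from
#' `Bernoulli(invlogit(true_beta0[wave] + true_beta1[wave] * ses + u))`.
#' Education is reported through the two parent columns (the mother's
#' category is the household maximum; the father's is drawn at or below it)
#' so that [resolve_household_education()] recovers the generating category.
#'
#' @param scenario A [new_scenario()].
#' @return A survey tibble in the [read_survey()] schema, reproducible given
#'   `scenario$seed`. The generating SES score and linear predictor are not
#'   included: the pipeline must reconstruct the score itself.
#' @export
generate_microdata <- function(scenario) {
  sc <- scenario
  set.seed(substream_seed(sc$seed, "microdata"))
  countries <- sprintf("C%02d", seq_len(sc$n_countries))
  n_waves <- length(sc$waves)

  # one row per respondent: country x wave x cluster x respondent
  frame <- tidyr::expand_grid(
    country_idx = seq_len(sc$n_countries),
    wave_idx = seq_len(n_waves),
    cluster_idx = seq_len(sc$clusters_per_country),
    resp_idx = seq_len(sc$respondents_per_cluster)
  )
  n <- nrow(frame)

  # education category per respondent, from the country's distribution
  edu <- integer(n)
  for (ci in seq_len(sc$n_countries)) {
    rows <- frame$country_idx == ci
    edu[rows] <- sample.int(sc$n_categories, sum(rows),
      replace = TRUE, prob = sc$ses_category_probs[ci, ]
    )
  }

  # pooled per-country fractional rank — the same rule the pipeline applies
  ses <- stats::ave(
    as.numeric(edu), frame$country_idx,
    FUN = function(e) rank(e, ties.method = "average") / length(e)
  )

  # cluster random intercepts: clusters are fresh in every wave
  cl_key <- interaction(frame$country_idx, frame$wave_idx, frame$cluster_idx,
    drop = TRUE
  )
  u_all <- stats::rnorm(nlevels(cl_key), 0, sc$sigma_u)
  u <- u_all[as.integer(cl_key)]

  eta <- sc$true_beta0[frame$wave_idx] + sc$true_beta1[frame$wave_idx] * ses + u
  outcome <- stats::rbinom(n, 1, stats::plogis(eta))
  gender <- ifelse(stats::runif(n) < sc$gender_split, "boy", "girl")
  edu_father <- as.integer(floor(stats::runif(n) * edu) + 1L) # uniform on 1..edu

  tibble::tibble(
    respondent_id = sprintf("R%07d", seq_len(n)),
    country = countries[frame$country_idx],
    cluster = sprintf(
      "%s-%d-K%02d", countries[frame$country_idx],
      sc$waves[frame$wave_idx], frame$cluster_idx
    ),
    year = sc$waves[frame$wave_idx],
    gender = gender,
    outcome = as.integer(outcome),
    edu_mother = as.integer(edu),
    edu_father = edu_father
  )
}

#' Read and write scenarios as YAML
#'
#' @param scenario A `scenario`.
#' @param path YAML file path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a validated `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$ses_category_probs <- apply(x$ses_category_probs, 1, as.numeric, simplify = FALSE)
  # precision = 17: lossless double round-trip, so a reloaded scenario
  # regenerates byte-identical micro-data
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  x$ses_category_probs <- do.call(rbind, x$ses_category_probs)
  do.call(new_scenario, x)
}
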