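#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. Values mirror the
#' method's defaults: 10,000 coefficient draws per stratum, a 5% eradication
#' threshold, gender stratification on, pooled per-country SES ranking and
#' 15 quadrature nodes.
#'
#' @param input Optional path to a survey CSV (ignored when data is passed
#'   to [run_pipeline()] directly).
#' @param outdir Optional output directory; when set, results, fits, figures
#'   and a run log are written there.
#' @param n_sim Coefficient draws per stratum (>= 100).
#' @param seed Master integer seed; per-stratum substreams are derived from
#'   it deterministically.
#' @param threshold Eradication cutoff in (0, 1).
#' @param stratify_gender Fit separately per gender (default `TRUE`)?
#' @param region_map `NULL` (no region stratification), `"default"` (the
#'   packaged UN-geoscheme map of European countries), a path to a CSV with
#'   columns `country` and `region`, or such a data frame.
#' @param rank_mode `"pooled"` or `"per-wave"` SES ranking (see
#'   [ses_rank()]).
#' @param quad_nodes Adaptive Gauss--Hermite nodes for the fits.
#' @param plots Write figures when `outdir` is set (default `TRUE`)?
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, outdir = NULL, n_sim = 10000, seed = 1,
                       threshold = 0.05, stratify_gender = TRUE,
                       region_map = NULL, rank_mode = c("pooled", "per-wave"),
                       quad_nodes = 15, plots = TRUE) {
  rank_mode <- match.arg(rank_mode)
  if (!is.numeric(n_sim) || n_sim < 100) {
    rlang::abort("n_sim must be at least 100", class = "ineqtrend_config_error")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must be in (0, 1)", class = "ineqtrend_config_error")
  }
  structure(
    list(
      input = input, outdir = outdir, n_sim = as.integer(n_sim),
      seed = as.integer(seed), threshold = threshold,
      stratify_gender = isTRUE(stratify_gender), region_map = region_map,
      rank_mode = rank_mode, quad_nodes = as.integer(quad_nodes),
      plots = isTRUE(plots)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @param ... Overrides applied on top of the file's values (e.g. CLI
#'   flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

resolve_region_map <- function(region_map) {
  if (is.null(region_map)) {
    return(NULL)
  }
  if (is.data.frame(region_map)) {
    check_columns(region_map, c("country", "region"), "region map")
    return(tibble::as_tibble(region_map))
  }
  path <- if (identical(region_map, "default")) {
    system.file("extdata", "region_map.csv", package = "ineqtrend", mustWork = TRUE)
  } else {
    region_map
  }
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(map, c("country", "region"), paste0("region map '", path, "'"))
  map
}

#' Run the full inequality-trend pipeline
#'
#' Executes every step of the method on one survey table: exclusion of
#' unusable records, fractional-rank SES scoring, a cluster random-intercept
#' logistic fit per stratum (wave by gender, for all countries combined and
#' per region when a region map is given), coefficient simulation,
#' prevalence pairs with confidence regions, the low-on-high prevalence
#' trend line, the simulation-based intercept interval and the eradication
#' likelihood, and a cross-stratum summary table. A stratum whose fit fails
#' is logged and dropped; the run fails only when no stratum survives.
#'
#' When `config$outdir` is set, the function writes `results.csv` (the
#' summary), `fits.json` (per-stratum coefficients and covariances),
#' `exclusions.json`, one figure per trend stratum, and `run.log`.
#'
#' @param data A survey tibble (as from [read_survey()] or
#'   [generate_microdata()]); when `NULL`, `config$input` is read.
#' @param config A [run_config()].
#' @return An object of class `ineq_run`: list with `config`, `exclusions`,
#'   `fits`, `pairs`, `regions`, `trends`, `summary`, `log` (character
#'   vector of log lines).
#' @export
run_pipeline <- function(data = NULL, config = run_config()) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  say("ineqtrend %s | R %s", as.character(utils::packageVersion("ineqtrend")), getRversion())
  say(
    "seed=%d n_sim=%d threshold=%g rank_mode=%s quad_nodes=%d",
    config$seed, config$n_sim, config$threshold, config$rank_mode, config$quad_nodes
  )

  if (is.null(data)) {
    if (is.null(config$input)) {
      rlang::abort("no data given and config$input is NULL", class = "ineqtrend_input_error")
    }
    data <- read_survey(config$input)
  }
  data <- exclude_incomplete(data)
  excl <- exclusion_report(data)
  say(
    "exclusions: %s",
    paste(sprintf("%s=%d", excl$reason, excl$n), collapse = " ")
  )
  scored <- ses_rank(data, mode = config$rank_mode)
  attr(scored, "exclusions") <- excl

  map <- resolve_region_map(config$region_map)
  if (!is.null(map)) {
    scored <- dplyr::left_join(scored, map, by = "country")
    unmapped <- unique(scored$country[is.na(scored$region)])
    if (length(unmapped) > 0) {
      say("countries missing from region map (kept in 'All countries' only): %s",
        paste(unmapped, collapse = ", "))
    }
    region_levels <- c("All countries", unique(map$region[map$region %in% scored$region]))
  } else {
    region_levels <- "All countries"
  }
  genders <- if (config$stratify_gender) sort(unique(scored$gender)) else "all"
  waves <- sort(unique(scored$year))

  fits <- list()
  pairs <- list()
  regions_out <- list()
  trends <- list()

  for (reg in region_levels) {
    reg_data <- if (reg == "All countries") scored else scored[!is.na(scored$region) & scored$region == reg, ]
    for (g in genders) {
      g_data <- if (identical(g, "all")) reg_data else reg_data[reg_data$gender == g, ]
      wave_pairs <- list()
      clouds <- list()
      for (w in waves) {
        stratum <- paste(reg, g, w, sep = "/")
        d <- g_data[g_data$year == w, ]
        if (nrow(d) == 0) {
          say("stratum %s: no data; skipped", stratum)
          next
        }
        fit <- tryCatch(
          withCallingHandlers(
            fit_cluster_logit(d, stratum = stratum, nodes = config$quad_nodes),
            warning = function(w2) {
              say("stratum %s: %s", stratum, conditionMessage(w2))
              invokeRestart("muffleWarning")
            },
            message = function(m) {
              say("stratum %s: %s", stratum, trimws(conditionMessage(m)))
              invokeRestart("muffleMessage")
            }
          ),
          error = function(e) {
            say("stratum %s: fit error: %s", stratum, conditionMessage(e))
            NULL
          }
        )
        if (is.null(fit)) next
        fits[[stratum]] <- fit
        if (!isTRUE(fit$converged)) {
          say("stratum %s: not converged; excluded from simulation", stratum)
          next
        }
        sseed <- substream_seed(config$seed, stratum)
        say("stratum %s: n=%d clusters=%d beta0=%.4f beta1=%.4f sigma_u=%.4f substream_seed=%d",
          stratum, fit$n_obs, fit$n_clusters, fit$beta0, fit$beta1, fit$sigma_u, sseed)
        draws <- draw_coefficients(fit, n_sim = config$n_sim, seed = sseed)
        pair <- prevalence_pair(fit, draws)
        pairs[[stratum]] <- pair
        regions_out[[stratum]] <- withCallingHandlers(
          confidence_region(draws),
          warning = function(w2) {
            say("stratum %s: %s", stratum, conditionMessage(w2))
            invokeRestart("muffleWarning")
          }
        )
        wave_pairs[[as.character(w)]] <- tibble::tibble(year = w, p1 = pair$p1, p0 = pair$p0)
        clouds[[as.character(w)]] <- dplyr::mutate(pair$cloud, wave = w)
      }
      if (length(wave_pairs) < 2) {
        say("stratum %s/%s: fewer than 2 fitted waves; no trend", reg, g)
        next
      }
      points <- dplyr::bind_rows(wave_pairs)
      sim_points <- dplyr::bind_rows(clouds)
      tr <- tryCatch(
        withCallingHandlers(
          eradication_likelihood(sim_points,
            threshold = config$threshold,
            points = points, stratum = paste(reg, g, sep = "/")
          ),
          message = function(m) {
            say("stratum %s/%s: %s", reg, g, trimws(conditionMessage(m)))
            invokeRestart("muffleMessage")
          }
        ),
        error = function(e) {
          say("stratum %s/%s: trend error: %s", reg, g, conditionMessage(e))
          NULL
        }
      )
      if (is.null(tr)) next
      tr$points <- points
      trends[[paste(reg, g, sep = "/")]] <- tr
      say(
        "trend %s/%s: slope=%.4f intercept=%.4f ci=(%.4f,%.4f) eradication=%.4f",
        reg, g, tr$line$slope, tr$line$intercept,
        tr$intercept_ci[1], tr$intercept_ci[2], tr$eradication_likelihood
      )
    }
  }

  if (length(fits) == 0 || length(trends) == 0) {
    rlang::abort(
      paste0(
        "pipeline produced no usable strata:\n",
        paste0("  ", log_lines, collapse = "\n")
      ),
      class = "ineqtrend_pipeline_error"
    )
  }

  result <- structure(
    list(
      config = config, exclusions = excl, fits = fits, pairs = pairs,
      regions = regions_out, trends = trends,
      summary = summarize_trends(trends), log = log_lines
    ),
    class = "ineq_run"
  )
  if (!is.null(config$outdir)) write_run(result, config$outdir)
  result
}

# Write the artifact bundle for a completed run.
write_run <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$summary, file.path(outdir, "results.csv"))
  write_fits(result$fits, file.path(outdir, "fits.json"))
  jsonlite::write_json(
    as.list(stats::setNames(result$exclusions$n, result$exclusions$reason)),
    file.path(outdir, "exclusions.json"),
    auto_unbox = TRUE
  )
  if (result$config$plots) {
    for (lab in names(result$trends)) {
      fname <- paste0("trend_", gsub("[^A-Za-z0-9]+", "_", lab), ".png")
      p <- autoplot_stratum(result, lab)
      grDevices::png(file.path(outdir, fname), width = 1600, height = 1600, res = 220)
      print(p)
      grDevices::dev.off()
    }
  }
  writeLines(result$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.ineq_run <- function(x, ...) {
  cat(sprintf(
    "Inequality-trend run: %d fitted strata, %d trend strata\n",
    length(x$fits), length(x$trends)
  ))
  writeLines(format_trend_table(x$summary))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.ineq_run <- function(x, ...) {
  x$summary
}

#' @rdname tidy
#' @export
glance.ineq_run <- function(x, ...) {
  tibble::tibble(
    n_strata_fitted = length(x$fits),
    n_strata_trend = length(x$trends),
    n_sim = x$config$n_sim,
    threshold = x$config$threshold,
    seed = x$config$seed
  )
}
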