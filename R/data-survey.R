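#' Column schema for survey micro-data files
#'
#' Maps the logical fields of an individual-level survey record to the column
#' names used in a delimited file. The logical fields are: `respondent_id`,
#' `country`, `cluster` (smallest known sampling unit: class, school or
#' country), `year` (survey wave), `gender`, `outcome` (binary, 1 = case),
#' `edu_mother` and `edu_father` (ordinal parental-education categories).
#'
#' @param ... Named overrides, e.g. `outcome = "smoker"` if the file calls the
#'   outcome column `smoker`.
#' @param edu_levels Optional character vector giving the ordered education
#'   categories from lowest to highest. When supplied, education columns are
#'   recoded to their integer position on this scale; values not on the scale
#'   (e.g. "don't know", "does not apply") become missing. When `NULL`,
#'   education columns must already be numeric category codes.
#' @param missing_codes Values (besides empty cells) read as missing.
#' @return A list with class `survey_schema`.
#' @examples
#' survey_schema(outcome = "weekly_smoker")
#' @export
survey_schema <- function(..., edu_levels = NULL, missing_codes = c("", "NA")) {
  fields <- c(
    "respondent_id", "country", "cluster", "year",
    "gender", "outcome", "edu_mother", "edu_father"
  )
  map <- stats::setNames(as.list(fields), fields)
  dots <- list(...)
  bad <- setdiff(names(dots), fields)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown schema field(s): ", paste(bad, collapse = ", ")),
      class = "ineqtrend_config_error"
    )
  }
  map[names(dots)] <- dots
  structure(
    list(map = map, edu_levels = edu_levels, missing_codes = missing_codes),
    class = "survey_schema"
  )
}

#' Read individual-level survey micro-data from CSV
#'
#' Reads a delimited file of one row per respondent, renames columns to the
#' logical schema, coerces types and validates every row. Rows that fail
#' validation are reported with their row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [survey_schema()].
#' @return A tibble with columns `respondent_id`, `country`, `cluster`,
#'   `year`, `gender`, `outcome`, `edu_mother`, `edu_father`. Education
#'   columns are integer category codes (1 = lowest) with `NA` for missing.
#' @seealso [write_survey()], [exclude_incomplete()]
#' @export
read_survey <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("input file not found: ", path), class = "ineqtrend_input_error")
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = schema$missing_codes, progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) {
    rlang::abort(paste0("input file is empty: ", path), class = "ineqtrend_input_error")
  }
  map <- schema$map
  check_columns(raw, unlist(map), what = paste0("file '", path, "'"))
  out <- tibble::tibble(
    respondent_id = raw[[map$respondent_id]],
    country = raw[[map$country]],
    cluster = raw[[map$cluster]],
    year = raw[[map$year]],
    gender = raw[[map$gender]],
    outcome = raw[[map$outcome]],
    edu_mother = raw[[map$edu_mother]],
    edu_father = raw[[map$edu_father]]
  )
  validate_survey(out, schema)
}

# Coerce the character columns of a raw survey table and fail with row
# numbers when values violate the record contract.
validate_survey <- function(data, schema = survey_schema()) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      more <- if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else ""
      problems <<- c(problems, sprintf("%s at row(s) %s%s", msg, shown, more))
    }
  }

  year <- suppressWarnings(as.integer(data$year))
  note(which(is.na(year) & !is.na(data$year)), "non-integer year")
  note(which(is.na(data$year)), "missing year")

  out_num <- suppressWarnings(as.numeric(data$outcome))
  bad_outcome <- which(!is.na(data$outcome) & (is.na(out_num) | !out_num %in% c(0, 1)))
  note(bad_outcome, "outcome not in {0, 1}")

  note(which(is.na(data$cluster)), "missing cluster")
  note(which(is.na(data$country)), "missing country")

  recode_edu <- function(x) {
    if (!is.null(schema$edu_levels)) {
      as.integer(match(x, schema$edu_levels))
    } else {
      v <- suppressWarnings(as.numeric(x))
      note(which(!is.na(x) & is.na(v)), "non-numeric education category")
      as.integer(v)
    }
  }
  edu_m <- recode_edu(data$edu_mother)
  edu_f <- recode_edu(data$edu_father)

  if (length(problems) > 0) {
    rlang::abort(
      paste0(
        "survey validation failed:\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      class = "ineqtrend_validation_error"
    )
  }

  tibble::tibble(
    respondent_id = as.character(data$respondent_id),
    country = as.character(data$country),
    cluster = as.character(data$cluster),
    year = year,
    gender = as.character(data$gender),
    outcome = as.integer(out_num),
    edu_mother = edu_m,
    edu_father = edu_f
  )
}

#' Write survey micro-data to CSV
#'
#' Inverse of [read_survey()] under the default schema: writing then reading
#' reproduces the table field for field.
#'
#' @param data A survey tibble as returned by [read_survey()] or
#'   [generate_microdata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(data, path) {
  check_columns(data, c(
    "respondent_id", "country", "cluster", "year",
    "gender", "outcome", "edu_mother", "edu_father"
  ))
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Highest completed education across both parents
#'
#' Collapses mother's and father's ordinal education categories to a single
#' household measure: the higher of the two. If one is missing the other is
#' used; if both are missing the result is missing. The operation is
#' symmetric in its two arguments.
#'
#' @param edu_mother,edu_father Integer (or ordered-factor) category codes,
#'   `NA` for missing.
#' @return Integer vector of household education categories.
#' @examples
#' resolve_household_education(c(3, NA, NA), c(5, 1, NA))
#' @export
resolve_household_education <- function(edu_mother, edu_father) {
  to_int <- function(x) if (is.ordered(x) || is.factor(x)) as.integer(x) else x
  m <- to_int(edu_mother)
  f <- to_int(edu_father)
  out <- pmax(m, f, na.rm = TRUE)
  out[is.na(m) & is.na(f)] <- NA
  as.integer(out)
}

#' Exclude records unusable for the inequality analysis
#'
#' Drops respondents with a missing outcome and respondents for whom both
#' parents' education is missing (no socioeconomic information at all), and
#' records the counts by reason. Adds the resolved household education as an
#' `edu` column for the survivors.
#'
#' @param data A survey tibble.
#' @return The filtered tibble with an `edu` column, carrying an
#'   `exclusions` attribute: a tibble of `reason` and `n` (retrievable with
#'   [exclusion_report()]).
#' @export
exclude_incomplete <- function(data) {
  check_columns(data, c("outcome", "edu_mother", "edu_father"))
  edu <- resolve_household_education(data$edu_mother, data$edu_father)
  miss_out <- is.na(data$outcome)
  miss_ses <- is.na(edu)
  report <- tibble::tibble(
    reason = c("missing_outcome", "missing_ses", "retained"),
    n = c(sum(miss_out), sum(miss_ses & !miss_out), sum(!miss_out & !miss_ses))
  )
  out <- data[!miss_out & !miss_ses, , drop = FALSE]
  out$edu <- edu[!miss_out & !miss_ses]
  attr(out, "exclusions") <- report
  out
}

#' Retrieve or write the exclusion report
#'
#' @param data A tibble returned by [exclude_incomplete()].
#' @return A tibble of exclusion counts by reason, or `NULL` when `data` has
#'   never been through [exclude_incomplete()].
#' @export
exclusion_report <- function(data) {
  attr(data, "exclusions")
}

#' @rdname exclusion_report
#' @param path Path for a JSON report of the counts.
#' @export
write_exclusion_report <- function(data, path) {
  rep <- exclusion_report(data)
  if (is.null(rep)) rlang::abort("no exclusion report attached; run exclude_incomplete() first")
  jsonlite::write_json(
    as.list(stats::setNames(rep$n, rep$reason)),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}
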