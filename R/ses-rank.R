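#' Fractional-rank socioeconomic score
#'
#' Converts the ordinal household-education category into a continuous
#' socioeconomic score in (0, 1], separately within each country. Respondents
#' are ranked by category; everyone in the same category receives the mean of
#' the ranks that category occupies (average-rank tie handling), and the rank
#' is divided by the number of scored respondents in the country. Within a
#' country, 0 represents the lowest possible and 1 the highest possible
#' parental education, so the score is comparable across countries with
#' different education distributions. This is the ranking used by the slope
#' and relative indices of inequality (SII/RII).
#'
#' Scores default to ranking each country's sample pooled over survey waves;
#' `mode = "per-wave"` ranks within each country-wave combination instead.
#'
#' @param data A survey tibble with columns `country` and `edu` (see
#'   [exclude_incomplete()]); `mode = "per-wave"` additionally requires
#'   `year`.
#' @param mode `"pooled"` (default) or `"per-wave"`.
#' @return `data` with an added numeric `ses` column in (0, 1].
#' @examples
#' d <- tibble::tibble(country = "A", edu = c(1, 1, 2, 2))
#' ses_rank(d)$ses # 0.375 0.375 0.875 0.875
#' @export
ses_rank <- function(data, mode = c("pooled", "per-wave")) {
  mode <- match.arg(mode)
  check_columns(data, c("country", "edu"))
  if (mode == "per-wave") check_columns(data, "year")
  if (any(is.na(data$edu))) {
    rlang::abort(
      "ses_rank() requires non-missing `edu`; run exclude_incomplete() first",
      class = "ineqtrend_validation_error"
    )
  }
  if (is.factor(data$country)) {
    empty <- setdiff(levels(data$country), unique(as.character(data$country)))
    if (length(empty) > 0) {
      rlang::warn(paste0(
        "no scored respondents for countr", if (length(empty) > 1) "ies: " else "y: ",
        paste(empty, collapse = ", "), "; stratum skipped"
      ))
    }
  }
  keys <- if (mode == "pooled") "country" else c("country", "year")
  out <- dplyr::mutate(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
    ses = rank(.data$edu, ties.method = "average") / dplyr::n()
  )
  dplyr::ungroup(out)
}
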