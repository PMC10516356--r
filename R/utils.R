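#' Inverse-logit and logit helpers
#'
#' Thin wrappers over [stats::plogis()] and [stats::qlogis()] so that model
#' code reads in the vocabulary of the method (probabilities at the extremes
#' of a 0--1 socioeconomic scale).
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @keywords internal
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @keywords internal
logit <- function(x) stats::qlogis(x)

# Deterministic 32-bit-safe substream seed from a master seed and a stratum
# label, so each stratum's simulation can be reproduced independently of the
# order in which strata are processed.
substream_seed <- function(master, label) {
  m <- 2147480009 # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  as.integer((as.numeric(master) %% m + h) %% m + 1)
}

# Stop unless `data` has all of `cols`; used by every table-first verb.
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "ineqtrend_config_error")
  }
  invisible(data)
}
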