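`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages in pipeline reports are rounded half-up to a fixed number of
#' decimals (271/295 -> 91.9, 80/82 -> 97.6), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop_validation("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_validation("'%s' must be a probability in [0, 1]", name)
  as.numeric(x)
}

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Aliases are deliberately not
#' resolved: matching is by plain symbol, case-insensitively, which is also
#' how human symbols are matched against mouse atlas symbols.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}
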