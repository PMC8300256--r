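#' Round half away from zero
#'
#' Commercial rounding used for display values: halves round away from zero
#' (so 0.145 -> 0.15, -0.145 -> -0.15), unlike [base::round()]'s banker's
#' rounding. All model quantities are carried at full precision; this is
#' applied only when formatting output to match printed conventions.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.145, -0.145), 2)
#' round_half_away(89.69) # 90
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fraction as an integer percent
#'
#' @param x Fraction in `[0, 1]` (or any numeric).
#' @return Character vector like `"90%"`, rounded half away from zero.
#' @export
#' @examples
#' percent(0.8969) # "90%"
percent <- function(x) {
  paste0(round_half_away(100 * x), "%")
}

# shared input checks --------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

check_count_vector <- function(x, name) {
  if (any(!is.na(x) & x < 0)) {
    abort(sprintf("`%s` contains negative counts.", name))
  }
  invisible(x)
}
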