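#' Annual per-capita growth rates from a yearly count series
#'
#' The per-capita growth rate for a pair of consecutive annual counts is the
#' natural-log ratio \eqn{r_t = \ln(N_{t+1}/N_t)}. By default the rate is
#' indexed by the *earlier* year of the pair (so `r_1993 = ln(N_1994/N_1993)`
#' is labelled 1993), which is the convention used in the worked growth-rate
#' calculations this package reproduces; set `convention = "later"` for the
#' alternative labelling.
#'
#' Pairs in which either count is zero or missing produce an `NA` rate (a
#' log-ratio touching zero is never emitted as `±Inf`), and a note listing
#' the affected years is attached as the `undefined_years` attribute.
#'
#' @param data A data frame with a `year` column and the count column named
#'   by `basis`, e.g. the output of [read_program_series()].
#' @param basis Which counts to use: `"surgeries"` (the population index) or
#'   `"census"` (direct counts). Must name a column of `data`.
#' @param convention `"earlier"` (default) or `"later"`: which year of the
#'   pair the rate is assigned to.
#' @return A tibble with one row per consecutive year pair: `year`, `count`
#'   (the count at the labelled year), and `rate`. Attributes `basis` and
#'   `convention` record the settings. A series of n counts yields n - 1
#'   rows.
#' @export
#' @examples
#' prog <- tibble::tibble(year = 1993:1995, surgeries = c(1768, 1630, 1104))
#' per_capita_growth_rates(prog) # r_1993 = ln(1630/1768) = -0.08
per_capita_growth_rates <- function(data,
                                    basis = c("surgeries", "census"),
                                    convention = c("earlier", "later")) {
  basis <- rlang::arg_match(basis)
  convention <- rlang::arg_match(convention)
  data <- as_tibble(data)
  if (!basis %in% names(data)) {
    abort(sprintf("`data` has no `%s` column.", basis))
  }
  if (nrow(data) < 2) {
    abort("Need at least 2 years of counts to compute growth rates.")
  }
  data <- dplyr::arrange(data, .data$year)
  n <- data[[basis]]
  from <- n[-length(n)]
  to <- n[-1]
  usable <- !is.na(from) & !is.na(to) & from > 0 & to > 0
  rate <- ifelse(usable, log(to / from), NA_real_)
  year <- if (convention == "earlier") data$year[-nrow(data)] else data$year[-1]
  count <- if (convention == "earlier") from else to
  out <- tibble(year = year, count = count, rate = rate)
  if (any(!usable)) {
    undef <- year[!usable]
    inform(sprintf(
      "Growth rate undefined (zero or missing count) for year(s): %s.",
      paste(undef, collapse = ", ")
    ))
    attr(out, "undefined_years") <- undef
  }
  attr(out, "basis") <- basis
  attr(out, "convention") <- convention
  out
}
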