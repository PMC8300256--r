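#' Monthly pregnancy proportions from per-cat surgery records
#'
#' Aggregates per-cat records into one row per calendar month containing at
#' least one female surgery: the number of female cats (all ages — kittens
#' count in the denominator) and the number of those found pregnant at
#' surgery. Males are never counted in either numerator or denominator.
#' Months with no female surgeries are simply absent.
#'
#' @param records A cat-record data frame (see [read_cat_records()]):
#'   columns `year`, `month`, `sex`, `pregnant`.
#' @param by Aggregation period: `"month"` (default, matching the monthly
#'   resolution of published pregnancy-proportion scatter) or `"year"`.
#' @return A tibble with columns `year`, `month` (absent when `by =
#'   "year"`), `month_index` (continuous months since the first record),
#'   `n_female`, `n_pregnant`, `proportion`.
#' @export
aggregate_pregnancy <- function(records, by = c("month", "year")) {
  by <- rlang::arg_match(by)
  records <- validate_cat_records(records)
  if (nrow(records) == 0) abort("`records` is empty.")
  females <- dplyr::filter(records, .data$sex == "female")
  if (nrow(females) == 0) {
    abort("No female records; pregnancy proportions undefined.")
  }
  origin <- min(12 * females$year + (females$month - 1))
  grouping <- if (by == "month") c("year", "month") else "year"
  out <- females |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_female = dplyr::n(),
      n_pregnant = sum(.data$pregnant %in% TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grouping)))
  out$month_index <- if (by == "month") {
    12 * out$year + (out$month - 1) - origin
  } else {
    12 * out$year - origin
  }
  out$proportion <- out$n_pregnant / out$n_female
  dplyr::relocate(out, "month_index", .before = "n_female")
}

#' Test for a time trend in the pregnancy proportion
#'
#' Regresses the monthly proportion of pregnant females (relative to all
#' female cats regardless of age) on a continuous month index by OLS, via
#' [proportion_trend()]. A proportion falling over the course of a program
#' indicates reduced fecundity — one of the four Ricker-model assessment
#' criteria.
#'
#' @param series Output of [aggregate_pregnancy()] (or any data frame with
#'   `n_pregnant`, `n_female` and `month_index` columns); needs at least 3
#'   periods.
#' @return A `tnr_trend` fit (see [fit_trend()]).
#' @export
pregnancy_trend_test <- function(series) {
  needed <- c("n_pregnant", "n_female", "month_index")
  if (!all(needed %in% names(series))) {
    abort(sprintf("`series` must have columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  if (nrow(series) < 3) abort("Need at least 3 periods.")
  proportion_trend(series, n_pregnant, n_female, month_index)
}
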