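#' Observed annual neutering fractions
#'
#' The fraction of the population sterilized each year: annual surgeries
#' divided by that year's estimated free-roaming population. With
#' `population_model = "census_regression"` (the default) the population is
#' estimated by fitting a line to the available census counts over year and
#' evaluating it in every program year (floored at 1 cat so the ratio stays
#' defined); `"census_raw"` uses the raw counts and leaves years without a
#' census absent. A zero-surgery year is a valid observation with fraction
#' 0; a missing or zero population estimate makes the fraction absent.
#'
#' @param data A program series with `year`, `surgeries` and `census`
#'   columns.
#' @param population_model `"census_regression"` or `"census_raw"`.
#' @return A tibble with columns `year`, `surgeries`,
#'   `population_estimate`, `fraction`; the median of the present fractions
#'   is stored in the `median_fraction` attribute.
#' @export
annual_neutering_fractions <- function(data,
                                       population_model = c("census_regression",
                                                            "census_raw")) {
  population_model <- rlang::arg_match(population_model)
  data <- as_tibble(data)
  if (!"census" %in% names(data) || all(is.na(data$census))) {
    abort(paste("No census data: supply population estimates to compute",
                "neutering fractions."))
  }
  data <- dplyr::arrange(data, .data$year)
  if (population_model == "census_regression") {
    have <- !is.na(data$census)
    if (sum(have) < 2) {
      abort("census_regression needs census counts for at least 2 years.")
    }
    fit <- lm(census ~ year, data = data[have, ])
    est <- pmax(unname(predict(fit, newdata = data["year"])), 1)
  } else {
    est <- as.numeric(data$census)
  }
  out <- tibble(
    year = data$year,
    surgeries = data$surgeries,
    population_estimate = est,
    fraction = ifelse(!is.na(est) & est > 0, data$surgeries / est, NA_real_)
  )
  attr(out, "median_fraction") <- median(out$fraction, na.rm = TRUE)
  attr(out, "population_model") <- population_model
  out
}

p_of <- function(fit) if (is.null(fit)) NA_real_ else fit$p_value

verdict_for <- function(fit, alpha) {
  if (is.null(fit)) return("not_available")
  if (is.na(fit$p_value)) return("not_available")
  if (fit$p_value < alpha && fit$slope < 0) "significant_decline"
  else "not_significant"
}

#' Assess a TNR program against the four Ricker-model criteria
#'
#' Runs the full assessment pipeline on a yearly program series (and
#' optional per-cat records): annual per-capita growth rates from the
#' surgery index (and from the census when present); the three trend
#' regressions — growth rate over time, growth rate vs annual surgeries
#' (with studentized-residual outlier exclusion, the fit that supplies
#' \eqn{r_m} as its y-intercept and the index carrying capacity K as its
#' x-intercept), and growth rate vs census population; the pregnancy
#' proportion trend when records are given; the Malthusian multiplier
#' \eqn{R_m = e^{r_m}}; the actual carrying capacity (index K scaled by
#' final-year population over final-year surgeries); survival from
#' lifespan; critical overall and annual neutering rates; and the observed
#' annual neutering fractions.
#'
#' Estimates of \eqn{r_m} and K always come from the growth-vs-surgeries
#' regression, never from the census fit. If that regression's slope is not
#' negative there is no density-dependent signal on the index scale: K,
#' \eqn{R_m} and the critical rates are reported as unavailable with an
#' explanatory note rather than fabricated.
#'
#' Each criterion present in the input yields a verdict at level
#' `config$alpha`: `significant_decline` (negative slope, p below alpha),
#' `not_significant`, or `not_available` when the data for it are missing.
#'
#' @param data A program series (see [read_program_series()]).
#' @param records Optional per-cat records (see [read_cat_records()]) for
#'   the pregnancy criterion.
#' @param lifespan Cat lifespan in years (>= 1) used for annual survival.
#' @param basis Whether `lifespan` is a `"median"` (default) or `"mean"`.
#' @param config A [tnr_config()].
#' @return An object of class `tnr_assessment`; see [render_report()],
#'   [tidy.tnr_assessment()], [glance.tnr_assessment()].
#' @export
assess_program <- function(data, records = NULL, lifespan = 5,
                           basis = c("median", "mean"),
                           config = tnr_config()) {
  basis <- rlang::arg_match(basis)
  data <- validate_program_series(as_tibble(data),
                                  program_id = attr(data, "program_id"))
  notes <- character(0)

  growth <- per_capita_growth_rates(data, basis = "surgeries",
                                    convention = config$rate_year_convention)
  note_fail <- function(what) {
    function(e) {
      notes <<- c(notes, sprintf("%s unavailable: %s", what,
                                 conditionMessage(e)))
      NULL
    }
  }
  growth_vs_time <- tryCatch(fit_trend(growth, year, rate),
                             error = note_fail("Growth-vs-time fit"))
  growth_vs_surgeries <- tryCatch(
    fit_trend(
      growth, count, rate,
      outlier_threshold = config$outlier_threshold,
      smoother = nrow(growth) >= 5,
      lowess_bandwidth = config$lowess_bandwidth,
      lowess_robust_iters = config$lowess_robust_iters
    ),
    error = note_fail("Growth-vs-surgeries fit")
  )

  has_census <- "census" %in% names(data) && sum(!is.na(data$census)) >= 3
  growth_vs_population <- NULL
  if (has_census) {
    census_rates <- per_capita_growth_rates(
      data[!is.na(data$census), ], basis = "census",
      convention = config$rate_year_convention
    )
    growth_vs_population <- tryCatch(
      fit_trend(census_rates, count, rate),
      error = function(e) NULL
    )
  }

  pregnancy <- NULL
  if (!is.null(records)) {
    pregnancy <- tryCatch(
      pregnancy_trend_test(aggregate_pregnancy(records)),
      error = function(e) {
        notes <<- c(notes, sprintf("Pregnancy trend unavailable: %s",
                                   conditionMessage(e)))
        NULL
      }
    )
  }

  # Ricker parameters from the surgery-index regression (y- and x-intercepts)
  r_m <- K_index <- R_m <- K_actual <- NA_real_
  if (!is.null(growth_vs_surgeries) &&
      !is.na(growth_vs_surgeries$slope) && growth_vs_surgeries$slope < 0) {
    r_m <- growth_vs_surgeries$intercept
    K_index <- growth_vs_surgeries$x_intercept
    R_m <- malthusian_multiplier(r_m)
    final <- if ("census" %in% names(data)) {
      dplyr::filter(data, !is.na(.data$census), .data$surgeries > 0)
    } else {
      data[0, ]
    }
    if (nrow(final) > 0 && !is.na(K_index) && K_index > 0) {
      final <- final[nrow(final), ]
      K_actual <- scale_carrying_capacity(K_index, final$census,
                                          final$surgeries)
    }
  } else if (!is.null(growth_vs_surgeries)) {
    notes <- c(notes, paste(
      "Growth-vs-surgeries slope is not negative: no density-dependent",
      "signal, so K, R_m and critical rates are not available."
    ))
  }

  survival <- survival_from_lifespan(lifespan, basis = basis)
  p <- survival$p
  s <- s_a <- NA_real_
  if (!is.na(R_m) && R_m > p) {
    s <- critical_neutering_rate(R_m, p)
    if (s <= 1) s_a <- critical_annual_rate(s, p)
  }

  neutering <- NULL
  if ("census" %in% names(data) && sum(!is.na(data$census)) >= 2) {
    neutering <- annual_neutering_fractions(data)
  }

  verdicts <- tibble(
    criterion = c("growth_vs_time", "growth_vs_surgeries",
                  "growth_vs_population", "pregnancy",
                  "malthusian_multiplier"),
    p_value = c(p_of(growth_vs_time), p_of(growth_vs_surgeries),
                p_of(growth_vs_population), p_of(pregnancy), NA_real_),
    verdict = c(
      verdict_for(growth_vs_time, config$alpha),
      verdict_for(growth_vs_surgeries, config$alpha),
      verdict_for(growth_vs_population, config$alpha),
      verdict_for(pregnancy, config$alpha),
      if (is.na(R_m)) "not_available"
      else if (R_m < 1) "significant_decline" else "not_significant"
    )
  )

  structure(
    list(
      program_id = attr(data, "program_id") %||% "program",
      data = data,
      growth = growth,
      growth_vs_time = growth_vs_time,
      growth_vs_surgeries = growth_vs_surgeries,
      growth_vs_population = growth_vs_population,
      pregnancy = pregnancy,
      r_m = r_m,
      R_m = R_m,
      K_index = K_index,
      K_actual = K_actual,
      survival = survival,
      s = s,
      s_a = s_a,
      neutering = neutering,
      verdicts = verdicts,
      notes = notes,
      config = config
    ),
    class = "tnr_assessment"
  )
}

# formatting helpers ---------------------------------------------------------

fmt_val <- function(x, digits = 2) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "N/A"
  else sprintf(paste0("%.", digits, "f"), round_half_away(x, digits))
}

fmt_p <- function(p) {
  if (is.na(p)) "N/A"
  else if (p < 1e-4) "p < 0.0001"
  else sprintf("p = %s", fmt_val(p))
}

fmt_verdict <- function(verdict, p) {
  switch(verdict,
    not_available = "N/A",
    significant_decline = sprintf("significant decline (%s)", fmt_p(p)),
    not_significant = sprintf("not significant (%s)", fmt_p(p))
  )
}

report_rows <- function(report) {
  v <- setNames(report$verdicts$verdict, report$verdicts$criterion)
  pv <- setNames(report$verdicts$p_value, report$verdicts$criterion)
  med <- if (is.null(report$neutering)) NA_real_
         else attr(report$neutering, "median_fraction")
  tibble(
    metric = c(
      "Per capita growth rate over time",
      "Per capita growth vs. annual surgeries",
      "Per capita growth vs. population",
      "Proportion of female cats pregnant",
      "Maximum per capita growth rate, rm",
      "Malthusian multiplier, Rm",
      "Index carrying capacity, K",
      "Actual carrying capacity",
      "Annual survival rate, p",
      "Critical overall neutering rate",
      "Critical annual neutering rate",
      "Observed median annual neutering fraction"
    ),
    value = c(
      fmt_verdict(v[["growth_vs_time"]], pv[["growth_vs_time"]]),
      fmt_verdict(v[["growth_vs_surgeries"]], pv[["growth_vs_surgeries"]]),
      fmt_verdict(v[["growth_vs_population"]], pv[["growth_vs_population"]]),
      fmt_verdict(v[["pregnancy"]], pv[["pregnancy"]]),
      fmt_val(report$r_m),
      fmt_val(report$R_m),
      fmt_val(report$K_index, 1),
      fmt_val(report$K_actual, 1),
      fmt_val(report$survival$p),
      fmt_val(report$s),
      fmt_val(report$s_a),
      fmt_val(med)
    )
  )
}

#' Serialize an assessment report
#'
#' Renders the criteria table of an assessment in the style of a published
#' key-metrics table: one row per criterion or derived quantity, p-values
#' and rates to 2 decimals, absent quantities as `N/A`. Identical inputs
#' and configuration produce byte-identical output. A parsed JSON report
#' (a data frame with `metric` and `value` columns) can be re-rendered,
#' so JSON round-trips to identical text.
#'
#' @param report A `tnr_assessment` from [assess_program()], or a data
#'   frame of rows from a previously rendered JSON report.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @return A single string (`text`, `csv`) or JSON string (`json`).
#' @export
render_report <- function(report, format = c("text", "csv", "json")) {
  format <- rlang::arg_match(format)
  if (inherits(report, "tnr_assessment")) {
    rows <- report_rows(report)
    header <- sprintf("TNR program assessment: %s", report$program_id)
  } else if (is.data.frame(report) &&
             all(c("metric", "value") %in% names(report))) {
    rows <- as_tibble(report)[c("metric", "value")]
    header <- "TNR program assessment"
  } else {
    abort("`report` must be a tnr_assessment or a metric/value data frame.")
  }
  switch(format,
    text = {
      width <- max(nchar(rows$metric))
      paste0(
        header, "\n",
        paste(sprintf(paste0("  %-", width, "s  %s"),
                      rows$metric, rows$value),
              collapse = "\n"),
        "\n"
      )
    },
    csv = readr::format_csv(rows),
    json = as.character(
      jsonlite::toJSON(rows, dataframe = "rows", pretty = TRUE)
    )
  )
}

#' @export
print.tnr_assessment <- function(x, ...) {
  cat(render_report(x, "text"))
  if (length(x$notes) > 0) {
    cat("Notes:\n")
    for (n in x$notes) cat("  -", n, "\n")
  }
  invisible(x)
}

#' Tidy and summary methods for assessments
#'
#' `tidy()` returns the per-criterion verdict table; `glance()` returns a
#' one-row tibble of the derived scalar quantities.
#'
#' @param x A `tnr_assessment`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tnr_assessment
#' @export
tidy.tnr_assessment <- function(x, ...) {
  x$verdicts
}

#' @rdname tidy.tnr_assessment
#' @method glance tnr_assessment
#' @export
glance.tnr_assessment <- function(x, ...) {
  tibble(
    program_id = x$program_id,
    r_m = x$r_m,
    R_m = x$R_m,
    K_index = x$K_index,
    K_actual = x$K_actual,
    survival_p = x$survival$p,
    critical_overall = x$s,
    critical_annual = x$s_a,
    observed_median_fraction = if (is.null(x$neutering)) NA_real_
                               else attr(x$neutering, "median_fraction")
  )
}

#' @rdname tidy.tnr_assessment
#' @param object A `tnr_assessment`.
#' @method autoplot tnr_assessment
#' @export
autoplot.tnr_assessment <- function(object, ...) {
  autoplot(object$growth_vs_surgeries) +
    ggplot2::labs(
      x = "annual surgeries",
      y = "per capita growth rate",
      title = sprintf("Density dependence on the surgery index: %s",
                      object$program_id)
    )
}
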