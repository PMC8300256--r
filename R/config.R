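#' Assessment run configuration
#'
#' Bundles every tunable of the assessment pipeline with its default:
#' significance level `alpha` 0.05; studentized-residual outlier cutoff 2;
#' Cleveland LOWESS settings (span 2/3, 3 robustifying iterations); the
#' earlier-year growth-rate labelling convention; 20 simulated years; and
#' half-away-from-zero display rounding (fixed — it is the convention the
#' printed percents use). The effective configuration is echoed in every
#' rendered report.
#'
#' @param alpha Two-sided significance level for the slope tests.
#' @param outlier_threshold Absolute studentized-residual cutoff for the
#'   growth-vs-surgeries fit; `Inf` disables exclusion.
#' @param lowess_bandwidth,lowess_robust_iters LOWESS settings.
#' @param rate_year_convention `"earlier"` or `"later"`; see
#'   [per_capita_growth_rates()].
#' @param simulation_years Horizon for Ricker simulations.
#' @param seed Optional integer seed recorded for generator runs.
#' @return A list of class `tnr_config`.
#' @export
tnr_config <- function(alpha = 0.05,
                       outlier_threshold = 2,
                       lowess_bandwidth = 2 / 3,
                       lowess_robust_iters = 3,
                       rate_year_convention = c("earlier", "later"),
                       simulation_years = 20,
                       seed = NULL) {
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(outlier_threshold, "outlier_threshold", min = 0, finite = FALSE)
  check_number(lowess_bandwidth, "lowess_bandwidth")
  check_number(simulation_years, "simulation_years", min = 1)
  structure(
    list(
      alpha = alpha,
      outlier_threshold = outlier_threshold,
      lowess_bandwidth = lowess_bandwidth,
      lowess_robust_iters = lowess_robust_iters,
      rate_year_convention = rlang::arg_match(rate_year_convention),
      simulation_years = simulation_years,
      percent_rounding = "half_away",
      seed = seed
    ),
    class = "tnr_config"
  )
}

#' @export
print.tnr_config <- function(x, ...) {
  cat("TNR assessment configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}
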