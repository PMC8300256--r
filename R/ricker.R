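#' Malthusian multiplier
#'
#' The annual multiplication factor of a population at vanishing density,
#' \eqn{R_m = e^{r_m}}, where \eqn{r_m} is the maximum per-capita rate of
#' increase. Under the Ricker model a population declines only when the
#' realized multiplier falls below 1. The value is returned at full
#' precision: downstream critical-rate calculations must carry the
#' unrounded multiplier (rounding \eqn{e^{0.16} = 1.1735} to 1.17 shifts a
#' critical rate by a whole percentage point).
#'
#' @param r_m Maximum per-capita growth rate (per year), finite.
#' @return `exp(r_m)`.
#' @export
#' @examples
#' malthusian_multiplier(0.16) # 1.1735...
malthusian_multiplier <- function(r_m) {
  check_number(r_m, "r_m")
  exp(r_m)
}

#' Annual survival rate from lifespan
#'
#' Approximates the annual survival probability as
#' \eqn{p = 1 - 1/\mathrm{lifespan}}. A mean lifespan of 5 years gives the
#' conventional p = 0.8; a median lifespan of 6 years gives p = 0.83.
#'
#' @param lifespan_years Lifespan in years, at least 1 (shorter lifespans
#'   would imply a negative survival rate under this approximation).
#' @param basis Whether the lifespan is a `"median"` (default) or `"mean"`;
#'   recorded alongside the rate.
#' @return A tibble with columns `lifespan_years`, `basis`, `p`.
#' @export
#' @examples
#' survival_from_lifespan(6) # p = 0.833
survival_from_lifespan <- function(lifespan_years,
                                   basis = c("median", "mean")) {
  basis <- rlang::arg_match(basis)
  check_number(lifespan_years, "lifespan_years")
  if (lifespan_years < 1) {
    abort("`lifespan_years` must be >= 1 (otherwise survival would be negative).")
  }
  tibble(lifespan_years = lifespan_years, basis = basis,
         p = 1 - 1 / lifespan_years)
}

#' Critical neutering rates
#'
#' `critical_neutering_rate()` gives the overall sterilized fraction of the
#' population required for decline, \eqn{s = (R_m - 1)/(R_m - p)};
#' `critical_annual_rate()` converts it to the fraction that must be
#' neutered *each year*, \eqn{s_a = s(1 - p)}, given annual survival p.
#' Both are returned at full precision; use [percent()] for printed-style
#' integer percents.
#'
#' @param R_m Malthusian multiplier, must exceed `p`.
#' @param p Annual survival rate in `[0, 1)`.
#' @param s Overall critical neutering fraction in `[0, 1]`.
#' @return A single fraction.
#' @export
#' @examples
#' s <- critical_neutering_rate(2.45, 1 - 1 / 6) # 0.897 -> "90%"
#' critical_annual_rate(s, 1 - 1 / 6) # 0.149 -> "15%"
critical_neutering_rate <- function(R_m, p) {
  check_number(R_m, "R_m")
  check_number(p, "p", min = 0)
  if (R_m <= p) {
    abort(sprintf(
      "Critical rate undefined: R_m (%.4g) must exceed survival p (%.4g).",
      R_m, p
    ))
  }
  (R_m - 1) / (R_m - p)
}

#' @rdname critical_neutering_rate
#' @export
critical_annual_rate <- function(s, p) {
  check_number(s, "s", min = 0, max = 1)
  check_number(p, "p", min = 0)
  if (p >= 1) abort("`p` must be < 1.")
  s * (1 - p)
}

#' Scale an index carrying capacity to actual cats
#'
#' When annual surgeries serve as a population index, the carrying capacity
#' estimated from the growth-rate regression is on the surgery-count scale.
#' It is converted to actual cats by multiplying by the final-year
#' free-roaming population and dividing by the final-year surgeries.
#'
#' @param K_index Index carrying capacity (surgery scale), positive.
#' @param final_population Free-roaming population in the final program year.
#' @param final_surgeries Surgeries in the final program year; must be
#'   positive (the index cannot be scaled in a zero-surgery year).
#' @return Carrying capacity in cats.
#' @export
#' @examples
#' scale_carrying_capacity(3.4, 10, 1) # 34
scale_carrying_capacity <- function(K_index, final_population,
                                    final_surgeries) {
  check_number(K_index, "K_index")
  check_number(final_population, "final_population", min = 0)
  check_number(final_surgeries, "final_surgeries", min = 0)
  if (K_index <= 0) abort("`K_index` must be positive.")
  if (final_surgeries == 0) {
    abort("Cannot scale the index carrying capacity in a zero-surgery year.")
  }
  K_index * final_population / final_surgeries
}

#' Deterministic Ricker-map simulation
#'
#' Iterates \eqn{N_{t+1} = N_t e^{r_m (1 - N_t/K)}} with real-valued
#' (unrounded) state for `years` annual steps, recording the annual
#' multiplier \eqn{R_t = e^{r_m(1 - N_t/K)}} at every year. State is never
#' rounded during iteration — the map is deterministic and continuous, and
#' rounding would alter trajectories; round for display only.
#'
#' Exactly one of `r_m` and `R_m` must be given (`r_m = log(R_m)`).
#'
#' @param r_m Maximum per-capita growth rate; or
#' @param R_m Malthusian multiplier (> 0).
#' @param K Carrying capacity (> 0) on whichever scale `N1` uses.
#' @param N1 Initial population (> 0).
#' @param years Number of years simulated, >= 1; the trajectory has `years`
#'   rows (years - 1 map applications).
#' @return A tibble of class `tnr_trajectory` with columns `year` (1-based),
#'   `N`, and `R` (the multiplier implied by that year's state). The
#'   dynamical regime from [classify_dynamics()] is stored in the `regime`
#'   attribute, and the parameters in `r_m` and `K` attributes.
#' @export
#' @examples
#' ricker_simulate(R_m = 1.57, K = 210325, N1 = 240690, years = 20)
ricker_simulate <- function(r_m = NULL, R_m = NULL, K, N1, years = 20) {
  if (is.null(r_m) == is.null(R_m)) {
    abort("Supply exactly one of `r_m` and `R_m`.")
  }
  if (!is.null(R_m)) {
    check_number(R_m, "R_m")
    if (R_m <= 0) abort("`R_m` must be positive.")
    r_m <- log(R_m)
  }
  check_number(r_m, "r_m")
  check_number(K, "K")
  check_number(N1, "N1")
  check_number(years, "years")
  if (K <= 0) abort("`K` must be positive.")
  if (N1 <= 0) abort("`N1` must be positive.")
  if (years < 1 || years != floor(years)) {
    abort("`years` must be a positive integer.")
  }

  N <- numeric(years)
  N[1] <- N1
  if (years > 1) {
    for (t in seq_len(years - 1)) {
      N[t + 1] <- N[t] * exp(r_m * (1 - N[t] / K))
    }
  }
  out <- tibble(
    year = seq_len(years),
    N = N,
    R = exp(r_m * (1 - N / K))
  )
  class(out) <- c("tnr_trajectory", class(out))
  attr(out, "r_m") <- r_m
  attr(out, "K") <- K
  attr(out, "regime") <- classify_dynamics(r_m)
  out
}

#' Classify the dynamical regime of the Ricker map
#'
#' Standard bifurcation structure of the Ricker map as a function of the
#' maximum per-capita growth rate: the fixed point K is approached
#' monotonically for `0 < r_m <= 1`, through damped oscillations for
#' `1 < r_m < 2`; at `r_m = 2` the fixed point loses stability in a
#' period-doubling cascade, and sustained chaos sets in near
#' `r_m = 2.6924`. Negative rates also give monotone decay (toward 0
#' rather than K).
#'
#' @param r_m Maximum per-capita growth rate, finite.
#' @return One of `"constant"`, `"monotone"`, `"damped_oscillation"`,
#'   `"periodic"`, `"chaotic"`.
#' @export
#' @examples
#' classify_dynamics(log(1.17)) # "monotone"
#' classify_dynamics(2.2) # "periodic"
classify_dynamics <- function(r_m) {
  check_number(r_m, "r_m")
  if (r_m == 0) {
    "constant"
  } else if (r_m <= 1) { # includes r_m < 0: monotone decay
    "monotone"
  } else if (r_m < 2) {
    "damped_oscillation"
  } else if (r_m < 2.6924) {
    "periodic"
  } else {
    "chaotic"
  }
}

#' @export
print.tnr_trajectory <- function(x, ...) {
  cat(sprintf(
    "Ricker trajectory: r_m = %.4g, K = %.6g, regime = %s\n",
    attr(x, "r_m"), attr(x, "K"), attr(x, "regime")
  ))
  NextMethod()
}

#' @rdname ricker_simulate
#' @param object A `tnr_trajectory`.
#' @param ... Unused.
#' @method autoplot tnr_trajectory
#' @export
autoplot.tnr_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$N)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "K"),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "year", y = "population",
                  title = sprintf("Ricker simulation (regime: %s)",
                                  attr(object, "regime")))
}
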