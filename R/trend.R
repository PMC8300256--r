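#' Fit a linear trend with optional residual-based outlier exclusion
#'
#' Ordinary least squares of `y` on `x` with the standard two-sided t-test
#' on the slope (df = n - 2). When the slope is negative the x-intercept
#' `-intercept/slope` is reported: in a growth-rate-vs-abundance regression
#' the y-intercept estimates the maximum per-capita rate of increase
#' \eqn{r_m} and the x-intercept estimates the index carrying capacity K.
#' For non-negative slopes the x-intercept is suppressed (a carrying
#' capacity is meaningless there).
#'
#' With a finite `outlier_threshold`, points whose internally studentized
#' residual exceeds the threshold in absolute value are flagged after an
#' initial fit and the model is refit once on the remainder — a single
#' exclusion round, never iterated. If exclusion would leave fewer than 3
#' points the unexcluded fit is returned with a warning.
#'
#' @param data A data frame.
#' @param x,y Columns of `data` (unquoted) holding predictor and response.
#' @param outlier_threshold Absolute studentized-residual cutoff; `Inf`
#'   (default) disables exclusion. The conventional cutoff used by the
#'   assessment pipeline is 2.
#' @param smoother If `TRUE`, attach a LOWESS curve (see [lowess_curve()])
#'   computed from the full data.
#' @param lowess_bandwidth,lowess_robust_iters LOWESS settings used when
#'   `smoother = TRUE`.
#' @return An object of class `tnr_trend`: a list with elements `slope`,
#'   `intercept`, `p_value`, `x_intercept` (`NA` unless slope < 0), `n_used`,
#'   `excluded` (tibble of removed points), `data` (points with an
#'   `excluded` flag), `model` (the fitted [stats::lm] object), `smoother`
#'   (tibble or `NULL`), and the axis names. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 0:4, y = 2 - 0.5 * 0:4)
#' fit <- fit_trend(d, x, y)
#' glance(fit) # slope -0.5, intercept 2, x_intercept 4
fit_trend <- function(data, x, y, outlier_threshold = Inf,
                      smoother = FALSE, lowess_bandwidth = 2 / 3,
                      lowess_robust_iters = 3) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  d <- tibble(
    x = as.numeric(data[[x_name]]),
    y = as.numeric(data[[y_name]])
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) abort("Need at least 3 complete (x, y) points.")
  if (length(unique(d$x)) < 2) abort("All x values are identical.")
  check_number(outlier_threshold, "outlier_threshold", min = 0,
               finite = FALSE)

  fit0 <- lm(y ~ x, data = d)
  excluded_idx <- integer(0)
  # residuals at floating-noise scale mean a perfect fit: studentized
  # residuals are then pure rounding error, so exclusion is skipped
  degenerate <- quiet_summary(fit0)$sigma <=
    max(1e-10, 1e-8 * stats::sd(d$y))
  if (is.finite(outlier_threshold) && !degenerate) {
    resid_std <- rstandard(fit0)
    flagged <- which(!is.na(resid_std) & abs(resid_std) > outlier_threshold)
    if (length(flagged) > 0) {
      if (nrow(d) - length(flagged) < 3) {
        warn("Outlier exclusion would leave fewer than 3 points; keeping all.")
      } else {
        excluded_idx <- flagged
      }
    }
  }
  keep <- setdiff(seq_len(nrow(d)), excluded_idx)
  fit <- if (length(excluded_idx) > 0) lm(y ~ x, data = d[keep, ]) else fit0

  est <- coef(fit)
  slope <- unname(est["x"])
  intercept <- unname(est["(Intercept)"])
  sm <- quiet_summary(fit)$coefficients
  p_value <- if ("x" %in% rownames(sm)) unname(sm["x", 4]) else NA_real_
  if (!is.finite(p_value)) p_value <- NA_real_
  x_intercept <- if (!is.na(slope) && slope < 0) -intercept / slope else NA_real_

  curve <- NULL
  if (isTRUE(smoother)) {
    curve <- lowess_curve(d, x, y, bandwidth = lowess_bandwidth,
                          robust_iters = lowess_robust_iters)
  }

  structure(
    list(
      slope = slope,
      intercept = intercept,
      p_value = p_value,
      x_intercept = x_intercept,
      n_used = length(keep),
      excluded = d[excluded_idx, , drop = FALSE],
      data = dplyr::mutate(d,
                           excluded = seq_len(nrow(d)) %in% excluded_idx),
      model = fit,
      smoother = curve,
      outlier_threshold = outlier_threshold,
      x_name = x_name,
      y_name = y_name
    ),
    class = "tnr_trend"
  )
}

#' LOWESS smoother evaluated at the observed x values
#'
#' Locally weighted scatterplot smoothing (Cleveland), used to check the
#' linearity assumption of the trend regressions. Defaults are the standard
#' Cleveland settings: a span of 2/3 and 3 robustifying iterations.
#'
#' @inheritParams fit_trend
#' @param bandwidth Smoother span, the fraction of points in each local
#'   window; must lie in (0, 1].
#' @param robust_iters Number of robustifying iterations (0 disables
#'   robustness weighting).
#' @return A tibble with columns `x` and `fitted`, sorted by `x`.
#' @export
lowess_curve <- function(data, x, y, bandwidth = 2 / 3, robust_iters = 3) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  d <- tibble(x = as.numeric(data[[x_name]]), y = as.numeric(data[[y_name]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 5) abort("LOWESS needs at least 5 points.")
  check_number(bandwidth, "bandwidth")
  if (bandwidth <= 0 || bandwidth > 1) {
    abort("`bandwidth` must be in (0, 1].")
  }
  check_number(robust_iters, "robust_iters", min = 0)
  sm <- lowess(d$x, d$y, f = bandwidth, iter = robust_iters)
  tibble(x = sm$x, fitted = sm$y)
}

#' Linear trend in a series of proportions
#'
#' Computes `numerator / denominator` per period and regresses the
#' proportion on time by OLS via [fit_trend()]. Periods with a zero or
#' missing denominator are skipped (they carry no proportion), reducing
#' `n_used`.
#'
#' @param data A data frame.
#' @param numerator,denominator,time Columns of `data` (unquoted):
#'   integer counts and a (possibly continuous) time axis.
#' @inheritParams fit_trend
#' @return A `tnr_trend` fit of proportion on time.
#' @export
proportion_trend <- function(data, numerator, denominator, time,
                             outlier_threshold = Inf) {
  num <- as.numeric(data[[rlang::as_name(rlang::enquo(numerator))]])
  den <- as.numeric(data[[rlang::as_name(rlang::enquo(denominator))]])
  tt <- as.numeric(data[[rlang::as_name(rlang::enquo(time))]])
  if (any(!is.na(num) & !is.na(den) & den > 0 & num > den)) {
    abort("`numerator` exceeds `denominator` for some period.")
  }
  usable <- !is.na(num) & !is.na(den) & !is.na(tt) & den > 0
  d <- tibble(time = tt[usable], proportion = num[usable] / den[usable])
  if (nrow(d) < 3) {
    abort("Fewer than 3 periods with a positive denominator.")
  }
  fit_trend(d, time, proportion, outlier_threshold = outlier_threshold)
}

# noise-free fits are legitimate here (exact-trajectory oracles); the
# perfect-fit caution from summary.lm is expected, not actionable
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# methods --------------------------------------------------------------------

#' @export
print.tnr_trend <- function(x, ...) {
  cat(sprintf("Linear trend: %s ~ %s\n", x$y_name, x$x_name))
  cat(sprintf("  slope     %.6g  (two-sided p = %s)\n", x$slope,
              format(x$p_value, digits = 3)))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  if (!is.na(x$x_intercept)) {
    cat(sprintf("  x-intercept %.6g\n", x$x_intercept))
  }
  cat(sprintf("  n used = %d, excluded = %d\n", x$n_used, nrow(x$excluded)))
  invisible(x)
}

#' @rdname fit_trend
#' @param x A `tnr_trend` object.
#' @param ... Unused.
#' @method tidy tnr_trend
#' @export
tidy.tnr_trend <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @rdname fit_trend
#' @method glance tnr_trend
#' @export
glance.tnr_trend <- function(x, ...) {
  tibble(
    slope = x$slope,
    intercept = x$intercept,
    p_value = x$p_value,
    x_intercept = x$x_intercept,
    r_squared = summary(x$model)$r.squared,
    n_used = x$n_used,
    n_excluded = nrow(x$excluded)
  )
}

#' @rdname fit_trend
#' @param object A `tnr_trend` object.
#' @method autoplot tnr_trend
#' @export
autoplot.tnr_trend <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$excluded),
                        show.legend = any(object$data$excluded)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey20", `TRUE` = "orange"),
      name = "excluded"
    ) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = object$x_name, y = object$y_name)
  if (!is.null(object$smoother)) {
    p <- p + ggplot2::geom_line(
      data = object$smoother,
      ggplot2::aes(x = .data$x, y = .data$fitted),
      colour = "firebrick", linetype = 2
    )
  }
  p
}
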