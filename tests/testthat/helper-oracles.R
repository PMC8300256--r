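# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::lm / stats::lowess) so that agreement
# is a genuine cross-check.

# OLS by explicit normal equations, with the slope t-test from first
# principles.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt((rss / (n - 2)) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# Tricube-weighted local linear regression at a single evaluation point —
# the definition LOWESS implements (robustness iterations off).
local_linear_oracle <- function(x, y, x0, f) {
  n <- length(x)
  q <- max(2, min(n, floor(f * n + 1e-7)))
  d <- abs(x - x0)
  h <- sort(d)[q]
  w <- ifelse(d <= h, (1 - pmin(1, (d / h))^3)^3, 0)
  W <- diag(w)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  drop(c(1, x0) %*% beta)
}

# Orbit-based regime detection for the Ricker map: iterate 500 steps and
# inspect the tail. Distinguishes a monotonically approached fixed point,
# a fixed point approached through damped alternation, a stable cycle of
# period <= 8, and aperiodic (chaotic) motion.
detect_regime_bruteforce <- function(r_m, K = 100, N1 = 37, steps = 500) {
  N <- numeric(steps)
  N[1] <- N1
  for (t in 1:(steps - 1)) N[t + 1] <- N[t] * exp(r_m * (1 - N[t] / K))
  tail100 <- N[(steps - 99):steps]
  if (max(abs(tail100 - K)) / K < 1e-8) {
    dev <- N - K
    idx <- utils::tail(which(abs(dev) / K > 1e-9), 20)
    alternations <- sum(diff(sign(dev[idx])) != 0)
    return(if (alternations >= 10) "damped_oscillation" else "monotone")
  }
  for (p in 2:8) {
    if (max(abs(tail100[-(1:p)] - tail100[1:(100 - p)])) / K < 1e-6) {
      return("periodic")
    }
  }
  "chaotic"
}

# Minimal per-cat record tibble builder for pregnancy tests.
make_records <- function(year, month, sex, pregnant = FALSE,
                         age_months = 24, outcome = "returned") {
  tibble::tibble(
    year = year, month = month, sex = sex,
    pregnant = pregnant, age_months = age_months, outcome = outcome
  )
}
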