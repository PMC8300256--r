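test_that("exact lines are recovered with x-intercept semantics", {
  d <- tibble::tibble(x = 0:4, y = 2 - 0.5 * (0:4))
  f <- fit_trend(d, x, y)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 2, tolerance = 1e-12)
  expect_equal(f$x_intercept, 4, tolerance = 1e-10)
  expect_equal(f$n_used, 5)

  flat <- fit_trend(tibble::tibble(x = 1:5, y = rep(3, 5)), x, y)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(flat$x_intercept)) # no carrying capacity without decline

  rising <- fit_trend(tibble::tibble(x = 1:5, y = 1:5), x, y)
  expect_true(is.na(rising$x_intercept))

  expect_error(fit_trend(tibble::tibble(x = 1:2, y = 1:2), x, y), "3")
  expect_error(fit_trend(tibble::tibble(x = rep(1, 4), y = 1:4), x, y),
               "identical")
})

test_that("OLS agrees with the normal-equation oracle on random data", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      x <- stats::rnorm(n, sd = sample(c(0.1, 1, 50), 1))
      y <- stats::rnorm(n, mean = 2 * x, sd = 1)
      f <- fit_trend(tibble::tibble(x = x, y = y), x, y)
      o <- ols_oracle(x, y)
      expect_equal(f$slope, o$slope, tolerance = 1e-9)
      expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
      expect_equal(f$p_value, o$p, tolerance = 1e-9)
    }
  })
})

test_that("p-value is invariant under affine rescaling of x", {
  withr::with_seed(11, {
    x <- stats::rnorm(15)
    y <- 1 - 0.3 * x + stats::rnorm(15, sd = 0.5)
    d <- tibble::tibble(x = x, y = y)
    d2 <- tibble::tibble(x = 100 + 7 * x, y = y)
    expect_equal(fit_trend(d, x, y)$p_value, fit_trend(d2, x, y)$p_value,
                 tolerance = 1e-10)
  })
})

test_that("studentized-residual exclusion removes planted outliers once", {
  n <- 20
  base_x <- seq(0, 10, length.out = n)
  clean <- tibble::tibble(x = base_x, y = 3 - 0.4 * base_x)

  # small noise so residual SD is defined, one gross outlier
  withr::with_seed(3, noise <- stats::rnorm(n, sd = 0.05))
  one <- clean
  one$y <- one$y + noise
  one$y[6] <- one$y[6] + 10 * stats::sd(noise)
  f1 <- fit_trend(one, x, y, outlier_threshold = 2)
  expect_equal(nrow(f1$excluded), 1)
  expect_equal(f1$excluded$x, base_x[6])
  expect_equal(f1$slope, -0.4, tolerance = 0.02)
  expect_equal(f1$n_used + nrow(f1$excluded), n)

  # two planted outliers, mirroring the two-outlier exclusion in the
  # published surgery-index regression
  two <- clean
  two$y <- two$y + noise
  two$y[c(4, 9)] <- two$y[c(4, 9)] + c(12, -14) * stats::sd(noise)
  f2 <- fit_trend(two, x, y, outlier_threshold = 2)
  expect_equal(nrow(f2$excluded), 2)
  expect_equal(f2$slope, -0.4, tolerance = 0.02)
  expect_equal(f2$intercept, 3, tolerance = 0.06)

  # exact line: zero residual variance, nothing to studentize or exclude
  f3 <- fit_trend(clean, x, y, outlier_threshold = 2)
  f0 <- fit_trend(clean, x, y)
  expect_equal(nrow(f3$excluded), 0)
  expect_equal(f3$slope, f0$slope)

  # threshold Inf is exactly fit without exclusion
  f4 <- fit_trend(two, x, y, outlier_threshold = Inf)
  expect_equal(nrow(f4$excluded), 0)
  expect_equal(f4$n_used, n)

  # exclusion that would leave < 3 points falls back with a warning
  tiny <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 10))
  expect_warning(ft <- fit_trend(tiny, x, y, outlier_threshold = 0.1),
                 "fewer than 3")
  expect_equal(ft$n_used, 3)
})

test_that("LOWESS reproduces lines, curvature, and the local oracle", {
  x <- seq(-1, 1, length.out = 21)
  line <- tibble::tibble(x = x, y = 1 + 2 * x)
  sm <- lowess_curve(line, x, y)
  expect_equal(sm$fitted, 1 + 2 * sm$x, tolerance = 1e-8)

  # global window, no robustness, exact line -> equals the OLS line
  sm1 <- lowess_curve(line, x, y, bandwidth = 1, robust_iters = 0)
  f <- fit_trend(line, x, y)
  expect_equal(sm1$fitted, f$intercept + f$slope * sm1$x, tolerance = 1e-8)

  # parabola: smoothed curve keeps the U shape
  par <- tibble::tibble(x = x, y = x^2)
  smp <- lowess_curve(par, x, y, bandwidth = 0.4, robust_iters = 0)
  expect_true(all(diff(smp$fitted[smp$x < -0.3]) < 0))
  expect_true(all(diff(smp$fitted[smp$x > 0.3]) > 0))
  # and matches direct tricube local-linear regression at interior points
  for (x0 in c(-0.5, 0, 0.5)) {
    expect_equal(smp$fitted[which.min(abs(smp$x - x0))],
                 local_linear_oracle(par$x, par$y, x0, f = 0.4),
                 tolerance = 1e-6)
  }

  expect_error(lowess_curve(line, x, y, bandwidth = 1.5), "bandwidth")
  expect_error(lowess_curve(line[1:4, ], x, y), "5")
})

test_that("proportion trends skip zero denominators and recover slopes", {
  d <- tibble::tibble(t = 1:10, num = rep(5, 10), den = rep(5, 10))
  f <- proportion_trend(d, num, den, t)
  expect_equal(f$slope, 0, tolerance = 1e-12) # proportions all 1

  dz <- tibble::tibble(t = 1:6, num = c(1, 2, 0, 2, 1, 2),
                       den = c(4, 4, 0, 4, 4, 4))
  fz <- proportion_trend(dz, num, den, t)
  expect_equal(fz$n_used, 5) # zero-denominator month skipped

  # binomial sampling around a known declining proportion
  withr::with_seed(21, {
    months <- 1:36
    p_true <- 0.5 - 0.01 * months
    num <- stats::rbinom(36, 500, p_true)
    db <- tibble::tibble(t = months, num = num, den = 500)
    fb <- proportion_trend(db, num, den, t)
    se <- tidy(fb)$std.error[2]
    expect_lt(abs(fb$slope - (-0.01)), 3 * se)
  })

  expect_error(proportion_trend(dz[1:3, ][-1, ], num, den, t), "3")
})

test_that("trend accessors expose a consistent broom-style surface", {
  d <- tibble::tibble(x = 1:8, y = 10 - 0.7 * (1:8) + c(0.01, -0.02, 0.03,
                                                        0, -0.01, 0.02,
                                                        -0.03, 0))
  f <- fit_trend(d, x, y)
  td <- tidy(f)
  gl <- glance(f)
  expect_named(td, c("term", "estimate", "statistic", "std.error",
                     "p.value")[c(1, 2, 4, 3, 5)], ignore.order = TRUE)
  expect_equal(gl$slope, td$estimate[td$term == "x"])
  expect_s3_class(autoplot(f), "ggplot")
})
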