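test_that("neutering fractions follow the census regression line", {
  flat <- tibble::tibble(year = 2000:2001, surgeries = c(10, 10),
                         census = c(100, 100))
  nf <- annual_neutering_fractions(flat)
  expect_equal(nf$fraction, c(0.1, 0.1))
  expect_equal(attr(nf, "median_fraction"), 0.1)

  # linear census decline 200 -> 100 over 11 years, constant 30 surgeries:
  # fractions climb monotonically from 0.15 to 0.30
  decl <- tibble::tibble(year = 2000:2010, surgeries = 30,
                         census = seq(200, 100, by = -10))
  nfd <- annual_neutering_fractions(decl)
  expect_equal(nfd$fraction[1], 0.15, tolerance = 1e-10)
  expect_equal(nfd$fraction[11], 0.30, tolerance = 1e-10)
  expect_true(all(diff(nfd$fraction) > 0))

  # a zero-surgery year is a real observation with fraction 0
  zed <- tibble::tibble(year = 2000:2002, surgeries = c(10, 0, 8),
                        census = c(50, 50, 50))
  expect_equal(annual_neutering_fractions(zed)$fraction[2], 0)

  # raw mode: missing or zero census years give absent fractions
  raw <- tibble::tibble(year = 2000:2002, surgeries = c(10, 10, 10),
                        census = c(50, NA, 0))
  nfr <- annual_neutering_fractions(raw, population_model = "census_raw")
  expect_equal(is.na(nfr$fraction), c(FALSE, TRUE, TRUE))

  no_census <- tibble::tibble(year = 2000:2002, surgeries = c(1, 2, 3))
  expect_error(annual_neutering_fractions(no_census), "census")
})

test_that("assessment recovers Ricker parameters from a noise-free program", {
  r_m <- 0.5
  K <- 400
  traj <- ricker_simulate(r_m = r_m, K = K, N1 = 20, years = 20)
  prog <- tibble::tibble(year = 1995:2014, surgeries = traj$N,
                         census = traj$N)
  a <- assess_program(prog, lifespan = 5, basis = "mean")
  expect_equal(a$r_m, r_m, tolerance = 1e-6)
  expect_equal(a$K_index, K, tolerance = 1e-6)
  expect_equal(a$R_m, exp(r_m), tolerance = 1e-6)
  # census equals the index here, so actual K equals index K
  expect_equal(a$K_actual, K, tolerance = 1e-6)
  expect_equal(a$s, critical_neutering_rate(exp(0.5), 0.8),
               tolerance = 1e-6)
  v <- tidy(a)
  expect_equal(v$verdict[v$criterion == "malthusian_multiplier"],
               "not_significant") # R_m > 1: no decline under the model
})

test_that("flat programs yield zero rates and unavailable Ricker fields", {
  prog <- tibble::tibble(year = 2000:2009, surgeries = rep(50, 10),
                         census = rep(120, 10))
  a <- suppressWarnings(assess_program(prog, lifespan = 5))
  expect_equal(a$growth$rate, rep(0, 9))
  expect_true(is.na(a$r_m))
  expect_true(is.na(a$s_a))
  v <- tidy(a)
  expect_equal(v$verdict[v$criterion == "growth_vs_time"],
               "not_available") # slope test undefined on constant rates
  expect_equal(v$verdict[v$criterion == "malthusian_multiplier"],
               "not_available")
  expect_true(any(grepl("not negative|unavailable", a$notes)))
})

test_that("criterion independence: dropping census touches only census fields", {
  sim <- generate_managed_program(managed_preset("orcat_like"), seed = 8)
  with_census <- suppressMessages(
    assess_program(sim$program, records = sim$records, lifespan = 6)
  )
  no_census <- suppressMessages(
    assess_program(dplyr::select(sim$program, -census),
                   records = sim$records, lifespan = 6)
  )
  expect_equal(no_census$growth_vs_surgeries$slope,
               with_census$growth_vs_surgeries$slope)
  expect_equal(no_census$growth_vs_time$p_value,
               with_census$growth_vs_time$p_value)
  expect_equal(no_census$pregnancy$p_value, with_census$pregnancy$p_value)
  expect_equal(no_census$r_m, with_census$r_m)
  expect_null(no_census$growth_vs_population)
  expect_null(no_census$neutering)
  expect_true(is.na(no_census$K_actual))
})

test_that("reports render deterministically across formats and round-trip", {
  sim <- generate_managed_program(managed_preset("ucf_like"), seed = 2)
  a <- suppressMessages(assess_program(sim$program, lifespan = 4))
  txt <- render_report(a, "text")
  expect_identical(txt, render_report(a, "text")) # byte-identical
  expect_match(txt, "Critical annual neutering rate")
  expect_match(txt, "N/A") # pregnancy records absent -> N/A cell

  parsed <- jsonlite::fromJSON(render_report(a, "json"))
  expect_identical(
    render_report(parsed, "text"),
    sub("assessment: [^\n]*", "assessment", txt)
  )

  csv <- readr::read_csv(I(render_report(a, "csv")), show_col_types = FALSE)
  expect_equal(names(csv), c("metric", "value"))
  expect_equal(nrow(csv), 12)
})

test_that("glance and autoplot expose the assessment surface", {
  sim <- generate_managed_program(managed_preset("orcat_like"), seed = 3)
  a <- suppressMessages(
    assess_program(sim$program, records = sim$records, lifespan = 6)
  )
  g <- glance(a)
  expect_equal(g$R_m, exp(a$r_m))
  expect_equal(g$critical_annual, a$s * (1 - a$survival$p))
  expect_s3_class(autoplot(a), "ggplot")
})
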