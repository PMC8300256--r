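---
title: "Assessing trap-neuter-return programs with a Ricker model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trap-neuter-return programs with a Ricker model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rickertnr)
library(dplyr)
```

## The model and what it is asked to do

Trap-neuter-return (TNR) programs sterilize free-roaming cats and return
them to their colonies, usually removing kittens and sociable cats for
adoption along the way. A recurring question is how much sterilization
effort such a program needs before the population declines, and one
influential answer comes from fisheries science: treat the population as a
discrete-time Ricker map,

$$N_{t+1} = N_t \, e^{r_m (1 - N_t / K)},$$

where $N_t$ is abundance in year $t$, $r_m$ is the maximum per-capita
growth rate (realized only at vanishing density), and $K$ is the carrying
capacity. The annual multiplier $R_t = e^{r_m(1 - N_t/K)}$ exceeds 1 below
capacity and falls short of it above — scramble-competition density
dependence. From a yearly count series the model's ingredients are
estimated through the per-capita growth rate

$$r_t = \ln(N_{t+1} / N_t),$$

regressed on abundance: the y-intercept of that regression estimates
$r_m$ and the x-intercept estimates $K$. The Malthusian multiplier is
$R_m = e^{r_m}$; a population declines under the model only if the
realized multiplier drops below 1. Given an annual survival rate $p$
(approximated from lifespan as $p = 1 - 1/\text{lifespan}$), the
sterilized fraction of the population needed for decline is

$$s = \frac{R_m - 1}{R_m - p}, \qquad s_a = s\,(1 - p),$$

where $s$ is the cumulative (overall) critical neutering rate and $s_a$
the fraction that must be newly neutered each year to sustain it.

This package implements that whole chain — growth rates, trend
regressions, critical rates, deterministic simulation — as a pipeline of
data-frame-in, tibble-out functions, together with a synthetic-data module
that generates program datasets with the statistical structure of
long-term TNR programs. The point of the synthetic module is adversarial
as much as illustrative: applied to a program whose census demonstrably
declines through sterilization-plus-adoption, the Ricker criteria largely
fail to register the decline. That model-mismatch demonstration is a
first-class, tested result of the package, not a by-product.

## The assessment criteria

`assess_program()` applies four criteria to a program series:

1. **Density-dependent regulation** — OLS of $r_t$ over time, from the
   surgery index.
2. **Fecundity change** — OLS of the monthly proportion of pregnant
   females (among all females at surgery, kittens included) on a
   continuous month index.
3. **Malthusian multiplier** — $R_m$ from the growth-vs-surgeries
   intercept; decline requires $R_m < 1$.
4. **Critical neutering rates** — $s$ and $s_a$ compared against the
   observed annual neutering fraction (surgeries divided by the
   census-regression population estimate).

Each criterion present in the data receives a verdict at $\alpha = 0.05$:
`significant_decline`, `not_significant`, or `not_available` when the
inputs for it are genuinely absent — a missing quantity is reported as
`N/A`, never imputed.

```{r example}
sim <- generate_managed_program(managed_preset("orcat_like"), seed = 1)
report <- assess_program(sim$program, records = sim$records, lifespan = 6)
report
```

## Conventions and tunable parameters

All tunables live in `tnr_config()` and are echoed in reports.

* **Year labelling of growth rates** (`rate_year_convention`, default
  `"earlier"`): $r_t$ uses the pair $(N_t, N_{t+1})$ and is labelled with
  the earlier year, matching the published worked example
  $r_{1993} = \ln(1630/1768) = -0.08$. The printed county tables are not
  fully consistent with either labelling (see below), so the convention
  is configurable and recorded in output attributes.
* **Outlier rule** (`outlier_threshold`, default 2): internally
  studentized residuals from a first fit; points beyond the threshold are
  removed and the model is refit exactly once. A single round is
  deliberate — iterating residual exclusion on 20-point series can chase
  noise. The threshold 2 is the common rule-of-thumb; the source analyses
  say only that outliers were "identified via residual analysis".
* **LOWESS** (`lowess_bandwidth` 2/3, `lowess_robust_iters` 3): standard
  Cleveland settings, used to check linearity rather than to estimate
  anything.
* **Significance** (`alpha` 0.05) and **display rounding**: model
  quantities are carried at full precision everywhere; printing uses
  half-away-from-zero rounding because that is what the published
  percents use. Carrying $R_m$ unrounded matters: $e^{0.16} = 1.1735$
  gives a 41% critical rate where the rounded 1.17 gives 40%.
* **Survival basis**: when both are available, median lifespan is
  preferred over mean, matching the source calculations for the two
  long-term programs ($p = 1 - 1/6 = 0.83$ for one, $1 - 1/4 = 0.75$ for
  the other).

Numerical edge cases are handled conservatively: log-ratios touching a
zero count are emitted as absent values (one program really did have a
zero-surgery year), never as infinities; a regression with zero residual
variance skips outlier flagging (studentized residuals there are pure
floating noise); the x-intercept is suppressed whenever the slope is
non-negative, because a "carrying capacity" read off an upward-sloping
fit is meaningless.

## The bundled fixtures and their known inconsistencies

`load_fixture()` ships the two county surgery tables and the
four-program simulation parameter table exactly as printed, typographic
minus signs included (they are normalized on read). The San Diego printed
growth-rate column is internally inconsistent with its own surgery
column: recomputing $\ln(N_{t+1}/N_t)$ reproduces the printed value for
some years (1993: $-0.08$) and contradicts it for others (1994: computed
$-0.39$ vs printed $-0.18$). `run_replication("foley_tables")` recomputes
every rate and flags each row, reproducing the documented discrepancies
rather than smoothing them over. Tests compare computed rates to printed
ones only where the two are consistent.

Two further printed values do not reconcile internally: $e^{0.89} = 2.435$
rounds to 2.44 yet 2.45 is printed throughout (the fixtures keep the
printed 2.45, since the underlying unrounded estimate is unknown), and
the prose "636% of carrying capacity" conflicts with the tabulated
$661/101 = 654\%$ (the fixtures follow the table).

A related known divergence: the prose describes the over-capacity
simulations as "collapse, rebound, then collapse again", but the
deterministic map with $r_m = \ln 2.45 \approx 0.90 < 1$ crashes once and
then converges monotonically to $K$ — there is no second collapse. The
simulator reproduces the map faithfully; `classify_dynamics()` gives the
regime (`monotone` here), with period-doubling at $r_m = 2$ and chaos
onset near $r_m = 2.6924$, the standard Ricker bifurcation values.

```{r simulate}
run_replication("table2_simulations")$orcat |> head(8)
```

## What the synthetic generators emulate — and what they do not

**Ricker regime** (`generate_ricker_program()`): a latent deterministic
Ricker trajectory observed through a proportional surgery index and a
census with multiplicative lognormal noise. This regime exists to close
the loop on estimation: with no noise, `assess_program()` recovers
$(r_m, K)$ to rounding error; with 5% census noise over 30 years the
median absolute error of $\hat r_m$ across 200 seeds stays well under
0.1. Recovery runs start well below $K$ (e.g. $N_1 = 0.1K$) because the
intercepts are identified by observations spanning low density; a series
that hovers near $K$ contains almost no information about $r_m$, which is
itself a caution about applying the method to managed populations.

**Managed-decline regime** (`generate_managed_program()`): the census
declines along a straight line (the observed long-term declines are
repeatedly characterized as linear) with Poisson jitter to keep counts
integral; surgeries are binomial draws at an annual neutering fraction
drawn lognormal (sdlog 0.5) about the configured median — the spread
calibrated once against the printed range of observed fractions (median
0.22, extremes 0.08 and 0.61); pregnancy probability declines linearly
per month; adoptions concentrate at kitten ages, lognormal about a median
of 4.8 months (sdlog 0.6, chosen since only the median is published).
Immigration defaults to zero: movement in and out of the area is exactly
what this model family omits, and no rate is published to calibrate one.
Presets `orcat_like` (455 to 206 cats over 22 years, fraction 0.22) and
`ucf_like` (68 to 10 over 28 years, fraction 0.16) encode the two
documented programs' endpoints.

All draws derive from one run seed (Mersenne-Twister) with per-year
sub-streams, so a year's draws do not shift when another year's record
count changes, and identical configurations reproduce bit-identically.

What the generators deliberately do **not** model: seasonality of
breeding, litter structure, survival differences between neutered and
intact cats, spatial colony structure, and immigration/abandonment
dynamics. Passing tests on this synthetic structure therefore show that
the pipeline's estimators and verdict logic behave as specified under the
stated assumptions — not that real colony data satisfy those assumptions.
Indeed the central demonstration is the opposite: even data constructed
to decline convincingly are mis-read by the Ricker criteria.

## The model-mismatch result

On `orcat_like` runs the census falls by roughly half, yet:

* the growth-rate-over-time regression is non-significant in the large
  majority of seeds (the rates hover around a small negative mean with
  year-to-year noise dominating);
* the estimated $R_m$ exceeds 1 essentially always, so criterion 3 calls
  the population non-declining — the regression-to-the-mean of a noisy
  surgery index produces a negative slope and a positive intercept
  regardless of the true dynamics;
* the observed median neutering fraction exceeds the computed critical
  annual rate, i.e. the program is doing "enough" by the model's own
  arithmetic while the model's trend criteria see nothing.

The test suite asserts these as inequalities across 100 seeds, and the
per-cat pregnancy records show the fecundity decline clearly
(significant at far below 0.05 in nearly all seeds), mirroring the one
criterion that did track reality.

## Problem sizes

The suite uses series of 20-30 years (matching real program durations),
100-200 seeds for stochastic properties, and 500-step orbits for
dynamical classification; the full suite and the acceptance script each
run in well under a minute of compute. These sizes were chosen so the
binomial/Poisson noise levels are realistic for programs of a few hundred
cats, not to make tests fast.

## Known limitations

* Proportions are regressed by plain OLS (as in the source analyses), not
  logistic regression; with monthly denominators of a handful of cats the
  proportion scatter is heteroscedastic, and p-values inherit that.
* No autocorrelation adjustment in the time regressions — replicating the
  original method is the point; the p-values should be read accordingly.
* The published regression p-values for the two long-term programs cannot
  be reproduced exactly because the underlying per-year datasets are
  available only on request; the calibrated presets reproduce the
  qualitative findings instead.
* The deterministic map has no demographic stochasticity; populations
  near zero (e.g. the over-capacity crash to ~4.6 cats) survive in the
  model where a real colony might not.
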