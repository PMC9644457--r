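---
title: "Methods: modelling household produce-purchasing trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling household produce-purchasing trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(producetrends)
```

## The problem

Grocery loyalty-card databases record every item a member household buys,
continuously, for years. That makes them attractive for population diet
surveillance: the share of fresh produce among a household's food purchases is
a frequency-based proxy for the healthfulness of the food available at home,
free of the recall and social-desirability errors of dietary self-report.
This package implements a complete analysis pipeline for such data — cleaning
rules, cohort construction, household-month aggregation, marginal trend
models, and descriptive census comparisons — together with a synthetic
transaction generator, because real loyalty-card extracts are proprietary and
cannot ship with analysis code.

## The outcome and the unit of analysis

For household $i$ in study month $j$, let $n_{ij}$ be the number of food
items purchased and $Y_{ij}$ the number of fresh produce items among them.
Each *unique* item in a transaction counts once, regardless of quantity, so
$Y_{ij}/n_{ij}$ is a purchase *frequency*, not a quantity or dollar share.
An item is fresh produce when it sits in the produce department under one of
thirteen fresh categories (bananas, berries, citrus, ...); frozen, dried,
canned, and juice items carried under the same department are food but not
produce. Months in which a household bought nothing contribute no row: missing
timepoints are left missing, not imputed.

## The trend model

The monthly produce share is modelled on the logit scale as an annual
harmonic plus a linear trend,

$$\mathrm{logit}\, E\!\left(\tfrac{Y_{ij}}{n_{ij}}\right) =
  \beta_0 + \beta_{S1} \sin\!\frac{2\pi t_{ij}}{12}
          + \beta_{S2} \cos\!\frac{2\pi t_{ij}}{12}
          + \beta_L t_{ij} + \beta_X X_i + \beta_{XL} X_i t_{ij},$$

with $t_{ij} \in \{1, \dots, 33\}$ the study month, $X_i$ the household's
demographic indicators (age group, income group, or their full interaction),
and $X_i t_{ij}$ giving each group its own linear trend. Estimation is by
generalized estimating equations with a *working independence* correlation:
the point estimates then solve exactly the weighted-logistic normal equations
(weights $n_{ij}$, outcomes $Y_{ij}/n_{ij}$), which `fit_produce_gee()`
solves by iteratively reweighted least squares. Households that buy more food
therefore weigh more, which also absorbs household-size effects.

Repeated months within a household are correlated, so all inference uses the
cluster-robust empirical sandwich covariance
$A^{-1} B A^{-1}$, where $A = X^\top W X$ is the binomial information
($W = n\,\mu(1-\mu)$) and $B$ sums outer products of within-household score
totals $\sum_j x_{ij}(Y_{ij} - n_{ij}\hat\mu_{ij})$. No small-sample
correction is applied: the intended cluster counts are in the
$10^3$–$10^5$ range, where such corrections are negligible.

Two outcome-scale summaries are derived per demographic cell, each with a
delta-method 95% interval using the robust covariance:

* **Baseline percent** — $100\,\mathrm{expit}(\hat\eta)$ at $t = 1$ *with*
  the seasonal terms evaluated at month 1, because the baseline names a
  calendar instant (the first January). The seasonally adjusted version is
  available via `include_seasonal = FALSE`.
* **Annual change** — the cell's per-month logit slope $\hat s$ (a linear
  contrast of $\beta_L$ and the applicable interactions), rescaled as the
  seasonal-free 12-month difference
  $100\,[\mathrm{expit}(\hat\eta_0 + 12\hat s) - \mathrm{expit}(\hat\eta_0)]$
  with $\hat\eta_0$ evaluated at the window midpoint ($t = 17$). A
  logit-scale slope has no single percent-per-year meaning on a curved link;
  anchoring the difference at the midpoint is the choice made here, isolated
  in `annual_change()` so an alternative rescaling is a one-function change.

```{r fit-example}
panel <- simulate_panel(600, seed = 42)
fit <- fit_produce_gee(panel, grouping = "age")
glance(fit)
annual_change(fit)
```

## Numerical choices

IRLS starts from the pooled logit (with a half-count continuity guard) and
stops when the relative coefficient change falls below $10^{-8}$, capped at
100 iterations; with working independence the solve is deterministic. Fitted
shares hitting the boundary ($\mu < 10^{-10}$) or runaway coefficients
($|\beta| > 30$) raise a separation flag and return the partial fit rather
than iterate to overflow. Dummy coding is against the youngest/lowest
reference levels (18–24, 0–14.9K); every reported contrast is re-expressed
per cell, so the reference choice is inert. Demographic groups absent from a
panel are dropped from the design rather than carried as all-zero columns;
contrasts then cover only the cells the data can speak about. Collinear
designs and zero-information fits are hard errors with diagnostics.

## The synthetic generator

The generator emulates the structure the analysis assumes, so every stage is
testable without proprietary data:

* **Demographics.** Nine raw income and six raw age groups with marginal
  shares whose collapsed margins equal the published cohort margins (income
  5.9 / 9.9 / 19.3 / 27.9 / 16.3 / 20.6%; age 2.8 / 14.2 / 35.1 / 36.8 /
  11.1%). The split of a collapsed group across its raw constituents is not
  identified by published margins; a roughly proportional split was chosen
  once. Missingness is 4% (age), 9% (income), and 15% (family flag and
  household size, blanked together), independent across field families —
  published sources state only marginal rates, so independence is assumed
  and documented here.
* **Purchasing.** Store visits per household-month are Poisson with mean 5.1
  (the published median visit frequency); items per visit are Poisson with
  mean 12, a realistic supermarket basket, giving roughly 58 retained food
  items per household-month. Neither value is published; both were fixed
  once.
* **Produce share.** Each retained food item is produce with probability
  given by the same logit model the fit estimates, so the generator and the
  model agree by construction (`dispersion = 1`). Cell baselines span
  12.2% (youngest age, lowest income) to 19.3% (oldest, highest); annual
  changes run from 1.42 down to 0.69 percent/year across income within the
  youngest group and essentially zero (0.03–0.05) for the oldest, matching
  the reported range of the motivating cohort. The harmonic amplitude is
  0.09 on the logit scale — a peak-to-trough swing of about 2.5 percentage
  points at a 17% share — with phase set to peak in May. Because a percent
  target and a logit slope are linked through the curved inverse logit, the
  per-month slope for each cell is solved by root-finding so that the true
  seasonal-free 12-month difference at the window midpoint equals the
  stated annual change, and the intercept is then anchored so the month-1
  (January, seasonal included) percent equals the stated baseline. A
  beta-binomial option (`dispersion > 1`) adds between-month overdispersion;
  the default stays exactly binomial so oracle tests are clean.
* **Removable items.** A configurable share of items (default 5%) exercises
  every exclusion rule — non-food departments, candy-making/pet-food/coupon
  patterns, beer kegs, produce trays of at least 1 lb, deli trays of at
  least 2 lb — and look-alikes that must be *retained* (sub-threshold trays,
  frozen produce) are generated among the food items. A small share of lines
  (1%) is emitted twice to exercise unique-item counting.

What the generator does **not** emulate: real between-household heterogeneity
within a demographic cell (all households in a cell share one mean curve),
price and promotion effects, basket composition beyond department labels,
day-of-week structure, and household attrition or address changes. Passing
tests therefore demonstrate that the pipeline recovers the truth of a
correctly specified data-generating process, not that the model fits any
particular real cohort.

`simulate_panel()` draws household-month binomial panels directly from the
generating model, skipping the transaction layer; simulation studies use it
because the transaction layer (tested separately for mean fidelity) adds cost
but no information about the estimator.

## Aggregation and descriptive summaries

The monthly series shows, per month and group, the item-weighted mean percent
produce — identical to the pooled $\sum Y / \sum n$ — with a design-based
95% interval using the between-household variance
$\sum w_i^2 (p_i - \bar p)^2 / (\sum w_i)^2$, which respects the household
as the sampling unit. The published figures state a 95% CI without a
construction; this estimator is this package's documented choice, not a claim
about the original. The grand mean $\sum Y / \sum n$ over all rows is the
reference line in the seasonal figures.

Descriptive tables use half-away-from-zero rounding at one decimal, matching
the published presentation. The census comparison applies a Pearson
chi-square to the loyalty-versus-ACS count contingency, treating both as
independent samples — an approximation, since loyalty households are a subset
of county households. The published age comparison sets household heads
against county *population* counts (the census does not report
head-of-household age); the layout is reproduced as printed, not harmonized.

```{r tables}
table_percentages(table3_income_counts(), axis = "column")
county_coverage_percent()
```

## Study window

The window runs January 2016 (month 1) through month 33 (September 2018 on a
strict count), although the motivating description names October 2018 — an
inclusive Jan 2016–Oct 2018 span would be 34 months. The package follows the
stated 33-month length and makes the window configurable
(`sim_config(study_months =, window_start =)`), rather than silently
reinterpreting either statement.

## Problem sizes used in the shipped checks

The test suite exercises marginal calibration and missingness at $10^5$
households, oracle equivalence against an independent weighted-GLM fit on a
500-household panel through the full transaction layer, a 200-replicate
parameter-recovery study at 1,000 households per replicate, and seasonal-shape
recovery at 2,000 households. The reproduction script uses a 1,200-household
end-to-end pipeline run for pooled quantities and a balanced 6,000-household
panel (200 households per age-by-income cell) for cell-level contrasts, so
every cell's estimate carries equal precision; these sizes give Monte-Carlo
error comfortably inside each quantity's comparison tolerance.

## Known limitations

Working independence is the only working correlation offered (inference is
robust to this, efficiency is not); there is no over-time model for December
and January, where harmonic fits of produce data typically over- and
under-shoot; the exclusion rules are list- and pattern-driven, not a
free-text classifier; and zip codes are a pass-through field with no
geography.
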