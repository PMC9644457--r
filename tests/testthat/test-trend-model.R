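test_that("design rows carry the harmonic identities and stated coding", {
  panel <- tidyr::expand_grid(age_group = age_levels(),
                              income_group = income_levels(),
                              month = c(1L, 3L)) |>
    dplyr::mutate(household_id = paste(age_group, income_group),
                  produce_items = 1L, total_items = 10L)
  d <- build_design(panel, grouping = "age_income")
  x <- d$x
  expect_equal(unname(x[, "sin12"]^2 + x[, "cos12"]^2), rep(1, nrow(x)))
  # t = 3: sin(pi/2) = 1, cos(pi/2) = 0; t = 12: sin 0, cos 1
  r3 <- which(panel$month == 3)
  expect_true(all(abs(x[r3, "sin12"] - 1) < 1e-12))
  expect_true(all(abs(x[r3, "cos12"]) < 1e-12))
  d12 <- build_design(dplyr::mutate(panel, month = 12), "none")
  expect_equal(unname(d12$x[1, "sin12"]), 0, tolerance = 1e-12)
  expect_equal(unname(d12$x[1, "cos12"]), 1)

  # full three-way expansion: 1 + 2 seasonal + (5x6 cell intercepts - 1 via
  # dummies) + as many slope columns
  expect_equal(ncol(x), 3 + 30 + 30 - 1)
  # reference levels are the youngest/lowest groups: no columns named for them
  expect_false(any(grepl("18-24|0-14.9K", colnames(x))))
  expect_error(build_design(dplyr::mutate(panel, age_group = "90+"), "age"),
               "levels")
})

test_that("intercept-only fit equals the logit of the pooled proportion", {
  panel <- small_panel(60, seed = 15)
  fit <- fit_produce_gee(panel, grouping = "none", include_seasonal = FALSE,
                         include_trend = FALSE)
  pooled <- sum(panel$produce_items) / sum(panel$total_items)
  expect_equal(unname(fit$coefficients), qlogis(pooled), tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("coefficients and robust covariance match the weighted-GLM oracle", {
  skip_if_not_installed("sandwich")
  panel <- small_panel(150, seed = 23)
  for (g in c("none", "age", "income")) {
    fit <- fit_produce_gee(panel, grouping = g)
    d <- build_design(panel, grouping = g)
    oracle <- glm(cbind(produce_items, total_items - produce_items) ~ 0 + d$x,
                  family = binomial, data = panel)
    expect_equal(unname(fit$coefficients), unname(coef(oracle)),
                 tolerance = 1e-8)
    vc <- sandwich::vcovCL(oracle, cluster = panel$household_id,
                           type = "HC0", cadjust = FALSE)
    expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(vc))),
                 tolerance = 1e-6)
  }
})

test_that("sandwich covariance is symmetric PSD and recomputable", {
  panel <- small_panel(80, seed = 29)
  fit <- fit_produce_gee(panel, grouping = "age")
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_equal(sandwich_covariance(fit), fit$vcov, tolerance = 1e-10)
})

test_that("with one observation per cluster and correct model, robust and model-based SEs agree", {
  tr <- produce_truth(baseline_matrix = matrix(17, 5, 6),
                      annual_change_matrix = matrix(0, 5, 6),
                      seasonal_sin = 0, seasonal_cos = 0)
  panel <- simulate_panel(8000, truth = tr, study_months = 1,
                          mean_items = 40, seed = 37)
  fit <- fit_produce_gee(panel, grouping = "none", include_seasonal = FALSE,
                         include_trend = FALSE)
  se_rob <- sqrt(diag(fit$vcov))
  se_mod <- sqrt(diag(fit$vcov_model))
  expect_lt(abs(se_rob / se_mod - 1), 0.05)
})

test_that("an all-zero response raises the separation flag", {
  panel <- small_panel(20, seed = 41)
  panel$produce_items <- 0L
  expect_warning(fit <- fit_produce_gee(panel, grouping = "none"),
                 "separation")
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_error(baseline_percent(fit), "converge")
})

test_that("wald intervals use the normal critical value", {
  ci <- wald_ci(0, 1)
  expect_equal(ci$ci_low, -1.959964, tolerance = 1e-6)
  expect_equal(ci$ci_high, 1.959964, tolerance = 1e-6)
  expect_equal(wald_ci(5, 0), tibble::tibble(estimate = 5, ci_low = 5,
                                             ci_high = 5))
  # interval consistent with a published-style rendering
  ci2 <- wald_ci(12.2, 0.561)
  expect_equal(round(ci2$ci_low, 1), 11.1)
  expect_equal(round(ci2$ci_high, 1), 13.3)
  expect_equal(format_estimate_ci(12.2, 11.1, 13.3), "12.2% (CI 11.1; 13.3)")
  expect_error(wald_ci(0, -1), "nonnegative")
})

test_that("contrasts reduce to expit identities in degenerate cases", {
  panel <- small_panel(60, seed = 43)
  fit <- fit_produce_gee(panel, grouping = "none")
  fit0 <- fit
  fit0$coefficients[] <- 0
  fit0$vcov[] <- 0
  expect_equal(baseline_percent(fit0)$estimate, 50)
  ac0 <- annual_change(fit0)
  expect_equal(ac0$estimate, 0)
  expect_equal(ac0$ci_low, 0)
  expect_equal(ac0$ci_high, 0)

  # no-trend fit cannot speak about annual change
  flatfit <- fit_produce_gee(panel, grouping = "none", include_trend = FALSE)
  expect_error(annual_change(flatfit), "no time trend")
})

test_that("baseline and annual-change contrasts recover the generating truth", {
  tr <- produce_truth()
  panel <- simulate_panel(3000, truth = tr, seed = 47)
  fit <- fit_produce_gee(panel, grouping = "age_income")
  base <- baseline_percent(fit)
  ac <- annual_change(fit)
  truth_base <- 100 * true_produce_percent(tr, base$age_group,
                                           base$income_group, 1)
  truth_ac <- tr$annual_change_matrix[cbind(ac$age_group, ac$income_group)]
  # truth inside the robust 95% interval for the vast majority of 30 cells
  cover_b <- mean(base$ci_low <= truth_base & truth_base <= base$ci_high)
  cover_a <- mean(ac$ci_low <= truth_ac & truth_ac <= ac$ci_high)
  expect_gte(cover_b, 0.8)
  expect_gte(cover_a, 0.8)
  # and the largest cells are tight
  big <- base$age_group == "55-74" & base$income_group == "50-74.9K"
  expect_lt(abs(base$estimate[big] -
                  100 * true_produce_percent(tr, "55-74", "50-74.9K", 1)), 0.5)
})

test_that("larger true slopes yield larger estimated annual changes", {
  slopes <- c(0.2, 0.8, 1.4)
  est <- vapply(seq_along(slopes), function(k) {
    tr <- produce_truth(baseline_matrix = matrix(15, 5, 6),
                        annual_change_matrix = matrix(slopes[k], 5, 6))
    panel <- simulate_panel(600, truth = tr, seed = 53) # common random numbers
    fit <- fit_produce_gee(panel, grouping = "none")
    annual_change(fit)$estimate
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("shifting the time origin leaves annual-change contrasts unchanged", {
  panel <- small_panel(120, seed = 59)
  fit1 <- fit_produce_gee(panel, grouping = "age")
  shifted <- dplyr::mutate(panel, month = month + 24) # same phase mod 12
  fit2 <- fit_produce_gee(shifted, grouping = "age")
  expect_false(isTRUE(all.equal(fit1$coefficients[1], fit2$coefficients[1])))
  expect_equal(annual_change(fit1)$estimate, annual_change(fit2)$estimate,
               tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom form", {
  panel <- small_panel(50, seed = 61)
  fit <- fit_produce_gee(panel, grouping = "age")
  td <- tidy(fit, conf.int = TRUE)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), length(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, dplyr::n_distinct(panel$household_id))
  expect_true(gl$converged)
})
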