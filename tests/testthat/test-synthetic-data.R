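test_that("config validation rejects malformed probability vectors and rates", {
  expect_error(sim_config(10, income_shares = rep(0.1, 9)), "summing to 1")
  expect_error(sim_config(10, age_shares = rep(1 / 5, 5)), "summing to 1")
  expect_error(sim_config(10, missing_rates = c(age = 0.1, income = 0.1)),
               "missing_rates")
  expect_error(sim_config(10, visits_per_month = 0))
  expect_silent(sim_config(10))
})

test_that("household generation is deterministic and honours missingness rates", {
  cfg <- sim_config(n_households = 500, seed = 42)
  hh1 <- simulate_households(cfg)
  hh2 <- simulate_households(cfg)
  expect_identical(hh1, hh2)
  expect_equal(nrow(hh1), 500)

  # degenerate rates leave no missing fields
  cfg0 <- sim_config(200, missing_rates = c(age = 0, income = 0, family = 0),
                     seed = 1)
  hh0 <- simulate_households(cfg0)
  expect_false(anyNA(hh0$age_group_raw))
  expect_false(anyNA(hh0$income_group_raw))
  expect_false(anyNA(hh0$household_size))

  # at n = 1e5 the empirical missingness is within 3 binomial SEs of target
  big <- simulate_households(sim_config(1e5, seed = 9))
  for (spec in list(c("age_group_raw", 0.04), c("income_group_raw", 0.09),
                    c("household_size", 0.15))) {
    rate <- as.numeric(spec[2])
    tol <- 3 * sqrt(rate * (1 - rate) / 1e5)
    expect_lt(abs(mean(is.na(big[[spec[1]]])) - rate), tol)
  }
  # family flag and size are blanked together
  expect_identical(is.na(big$family), is.na(big$household_size))
})

test_that("demographic margins converge to the configured shares", {
  big <- simulate_households(sim_config(1e5, seed = 13))
  inc <- table(big$.income_true)[income_levels_raw()] / 1e5
  age <- table(big$.age_true)[age_levels_raw()] / 1e5
  for (k in seq_along(income_levels_raw())) {
    p <- default_income_shares()[k]
    expect_lt(abs(inc[k] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
  for (k in seq_along(age_levels_raw())) {
    p <- default_age_shares()[k]
    expect_lt(abs(age[k] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("generating mean follows the closed-form logit model", {
  # zero coefficients: flat 50% every month
  flat <- produce_truth(baseline_matrix = matrix(50, 5, 6),
                        annual_change_matrix = matrix(0, 5, 6),
                        seasonal_sin = 0, seasonal_cos = 0)
  expect_equal(true_produce_percent(flat, "35-54", "50-74.9K", 1:33),
               rep(0.5, 33))

  # no seasonality or trend: the baseline percent holds every month
  p17 <- produce_truth(baseline_matrix = matrix(17, 5, 6),
                       annual_change_matrix = matrix(0, 5, 6),
                       seasonal_sin = 0, seasonal_cos = 0)
  expect_equal(true_produce_percent(p17, "18-24", "0-14.9K", 1:33),
               rep(0.17, 33))

  # hand evaluation of the closed form at t = 6 with nonzero harmonics
  tr <- produce_truth(baseline_matrix = matrix(17, 5, 6),
                      annual_change_matrix = matrix(0, 5, 6),
                      seasonal_sin = 0.1, seasonal_cos = -0.05)
  seas1 <- 0.1 * sin(2 * pi / 12) - 0.05 * cos(2 * pi / 12)
  expected <- plogis(qlogis(0.17) - seas1 +
                       0.1 * sin(2 * pi * 6 / 12) - 0.05 * cos(2 * pi * 6 / 12))
  expect_equal(true_produce_percent(tr, "25-34", "75-99.9K", 6), expected)

  # the baseline anchor: month-1 seasonal-included percent equals the matrix
  tr2 <- produce_truth()
  expect_equal(100 * true_produce_percent(tr2, "18-24", "0-14.9K", 1), 12.2)
  expect_equal(100 * true_produce_percent(tr2, "75-89", ">=100K", 1), 19.3)
  expect_error(true_produce_percent(tr2, "17-24", "0-14.9K", 1), "cell")
})

test_that("true annual change matches its defining 12-month contrast", {
  tr <- produce_truth()
  t_mid <- 17
  for (cell in list(c("18-24", "0-14.9K"), c("75-89", ">=100K"))) {
    s <- tr$slope_matrix[cell[1], cell[2]]
    eta0 <- tr$intercept_matrix[cell[1], cell[2]] + s * t_mid
    measured <- 100 * (plogis(eta0 + 12 * s) - plogis(eta0))
    expect_equal(measured, tr$annual_change_matrix[cell[1], cell[2]],
                 tolerance = 1e-8)
  }
})

test_that("transactions are deterministic and follow the generating mean", {
  cfg <- sim_config(60, seed = 21)
  hh <- simulate_households(cfg)
  expect_identical(simulate_transactions(hh, cfg),
                   simulate_transactions(hh, cfg))

  # flat truth: pooled produce share among retained food items within 3 SE
  flat <- produce_truth(baseline_matrix = matrix(20, 5, 6),
                        annual_change_matrix = matrix(0, 5, 6),
                        seasonal_sin = 0, seasonal_cos = 0)
  cfg2 <- sim_config(80, truth = flat, seed = 3, duplicate_share = 0)
  hh2 <- simulate_households(cfg2)
  it2 <- simulate_transactions(hh2, cfg2)
  kept <- classify_produce(apply_exclusions(it2, hh2))
  phat <- mean(kept$is_produce)
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(kept)))
})

test_that("zero filter share leaves only everyday food items", {
  cfg <- sim_config(25, filter_share = 0, duplicate_share = 0, seed = 8)
  hh <- simulate_households(cfg)
  items <- simulate_transactions(hh, cfg)
  cleaned <- apply_exclusions(items, hh)
  log <- removal_log(cleaned)
  expect_equal(sum(log$items[log$rule != "retained"]), 0)
  expect_equal(nrow(cleaned), nrow(items))
})

test_that("months without visits leave no panel row", {
  cfg <- sim_config(40, visits_per_month = 0.25, filter_share = 0,
                    duplicate_share = 0, seed = 5)
  hh <- simulate_households(cfg)
  items <- simulate_transactions(hh, cfg)
  cohort <- collapse_demographics(complete_case_filter(hh))
  panel <- build_panel(classify_produce(items), cohort, warn_dropped = FALSE)
  months_with_items <- dplyr::distinct(
    dplyr::semi_join(items, cohort, by = "household_id"),
    household_id, month = month_index(date))
  expect_equal(nrow(panel), nrow(months_with_items))
  expect_lt(nrow(panel), nrow(cohort) * 33) # some timepoints genuinely absent
})

test_that("panel simulator hits the generating mean cell by cell", {
  tr <- produce_truth()
  panel <- simulate_panel(4000, truth = tr, seed = 77)
  by_cell <- panel |>
    dplyr::filter(month == 1) |>
    dplyr::group_by(age_group, income_group) |>
    dplyr::summarise(phat = sum(produce_items) / sum(total_items),
                     n = sum(total_items), .groups = "drop")
  p_true <- true_produce_percent(tr, by_cell$age_group, by_cell$income_group, 1)
  z <- abs(by_cell$phat - p_true) / sqrt(p_true * (1 - p_true) / by_cell$n)
  expect_lt(mean(z > 3), 0.1) # a 3-sigma bound per cell, allow rare excursions
  expect_lt(max(z[by_cell$n > 2e4]), 4)
})
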