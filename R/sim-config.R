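#' Configuration for the synthetic loyalty-card generator
#'
#' Bundles every knob of the transaction simulator. The defaults are the study
#' conditions the package is calibrated to: a 33-month window starting January
#' 2016, demographic marginals matching the loyalty-card cohort's collapsed
#' margins, 4%/9%/15% missingness on age / income / family-and-size fields, a
#' median-like 5.1 store visits per household-month, and the
#' [produce_truth()] generating model.
#'
#' @param n_households Number of households to simulate.
#' @param study_months Length of the study window in months (default 33).
#' @param window_start First day of the first study month (default 2016-01-01).
#' @param income_shares Probability vector over the nine raw income groups.
#' @param age_shares Probability vector over the six raw age groups.
#' @param missing_rates Named probabilities `c(age=, income=, family=)` that a
#'   household's age, income, or family-and-size fields are missing. The
#'   family rate blanks the family flag and household size together; fields
#'   are missing independently of one another.
#' @param visits_per_month Mean store visits per household-month (Poisson).
#' @param items_per_visit Mean items per store visit (Poisson; zero-item
#'   visits leave no item rows).
#' @param filter_share Probability that a generated item is one of the
#'   removable kinds the preprocessing rules target (non-food department,
#'   non-food pattern in a food department, beer keg, at-threshold produce or
#'   deli party tray). Set 0 for a clean food-only stream.
#' @param duplicate_share Probability that an item line is scanned twice,
#'   producing a duplicate row that unique-item counting must collapse.
#' @param truth A [produce_truth()] object; its `study_months` must match.
#' @param n_stores Number of store identifiers to draw from.
#' @param seed Master seed; each generated table uses its own stream split
#'   from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_households = 50, seed = 1)
#' @export
sim_config <- function(n_households,
                       study_months = 33,
                       window_start = as.Date("2016-01-01"),
                       income_shares = default_income_shares(),
                       age_shares = default_age_shares(),
                       missing_rates = c(age = 0.04, income = 0.09, family = 0.15),
                       visits_per_month = 5.1,
                       items_per_visit = 12,
                       filter_share = 0.05,
                       duplicate_share = 0.01,
                       truth = produce_truth(study_months = study_months),
                       n_stores = 17,
                       seed = 1L) {
  check_share_vector(income_shares, 9L, "income_shares")
  check_share_vector(age_shares, 6L, "age_shares")
  stopifnot(is.numeric(n_households), length(n_households) == 1,
            n_households >= 1,
            is.numeric(study_months), study_months >= 1,
            inherits(window_start, "Date"),
            is.numeric(visits_per_month), visits_per_month > 0,
            is.numeric(items_per_visit), items_per_visit > 0,
            filter_share >= 0, filter_share < 1,
            duplicate_share >= 0, duplicate_share < 1,
            inherits(truth, "produce_truth"),
            n_stores >= 1, is.numeric(seed), length(seed) == 1)
  if (!setequal(names(missing_rates), c("age", "income", "family")) ||
      any(missing_rates < 0) || any(missing_rates > 1)) {
    abort("`missing_rates` must be probabilities named age, income, family")
  }
  structure(list(n_households = as.integer(n_households),
                 study_months = as.integer(study_months),
                 window_start = window_start,
                 income_shares = income_shares, age_shares = age_shares,
                 missing_rates = missing_rates[c("age", "income", "family")],
                 visits_per_month = visits_per_month,
                 items_per_visit = items_per_visit,
                 filter_share = filter_share,
                 duplicate_share = duplicate_share,
                 truth = truth, n_stores = as.integer(n_stores),
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_share_vector <- function(x, len, what) {
  if (!is.numeric(x) || length(x) != len || any(x < 0) ||
      abs(sum(x) - 1) > 1e-12) {
    abort(sprintf("`%s` must be %d nonnegative probabilities summing to 1",
                  what, len))
  }
  invisible(x)
}

#' Default demographic marginal shares
#'
#' Marginal shares over the raw nine income and six age groups. The collapsed
#' margins they imply match the loyalty-card cohort's printed margins (income
#' 5.9/9.9/19.3/27.9/16.3/20.6%, age 2.8/14.2/35.1/36.8/11.1%); the split of
#' each collapsed group across its raw constituents is not identified by those
#' margins and uses a roughly proportional allocation chosen once. Vectors are
#' normalised to sum to exactly 1.
#'
#' @return A named probability vector.
#' @export
default_income_shares <- function() {
  x <- c(5.9, 4.0, 5.9, 9.6, 9.7, 27.9, 16.3, 12.6, 8.0)
  setNames(x / sum(x), income_levels_raw())
}

#' @rdname default_income_shares
#' @export
default_age_shares <- function() {
  x <- c(2.8, 14.2, 17.5, 17.6, 36.8, 11.1)
  setNames(x / sum(x), age_levels_raw())
}

#' @rdname default_income_shares
#' @export
default_household_size_shares <- function() {
  x <- c(18.3, 23.7, 23.9, 15.6, 9.7, 8.8)
  setNames(x / sum(x), c("1", "2", "3", "4", "5", "6+"))
}
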