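#' Build the household-month binomial panel
#'
#' Counts, for every household and study month with at least one retained
#' food item, the number of fresh produce items (`produce_items`) out of all
#' food items (`total_items`). Each unique food item in a transaction counts
#' once regardless of quantity: item lines are first deduplicated on
#' (`transaction_id`, `item_description`, `class`). Items from households not
#' in the cohort are dropped (their count is attached as attribute
#' `"dropped_items"`); households with no purchases in a month simply have no
#' row for it.
#'
#' @param items Cleaned transaction items (post [apply_exclusions()]); the
#'   `is_produce` column is added via [classify_produce()] if absent.
#' @param cohort Analysis households carrying `household_id`, `age_group`,
#'   `income_group`.
#' @param window_start First day of study month 1.
#' @param study_months Window length in months.
#' @param warn_dropped Warn when out-of-cohort items are dropped (default
#'   `TRUE`; the pipeline silences it because complete-case filtering makes
#'   such drops routine).
#' @return A tibble: `household_id`, `month`, `produce_items`, `total_items`,
#'   `age_group`, `income_group`.
#' @export
build_panel <- function(items, cohort, window_start = as.Date("2016-01-01"),
                        study_months = 33, warn_dropped = TRUE) {
  stopifnot(all(c("household_id", "transaction_id", "date",
                  "item_description") %in% names(items)),
            all(c("household_id", "age_group", "income_group") %in%
                  names(cohort)))
  items <- tibble::as_tibble(items)
  if (!("is_produce" %in% names(items))) items <- classify_produce(items)
  if (!("class" %in% names(items))) items$class <- ""

  items <- dplyr::distinct(items, .data$transaction_id,
                           .data$item_description, .data$class,
                           .keep_all = TRUE)
  in_cohort <- items$household_id %in% cohort$household_id
  dropped <- sum(!in_cohort)
  if (dropped > 0 && warn_dropped) {
    warn(sprintf("%d items from households outside the cohort dropped",
                 dropped))
  }
  items <- items[in_cohort, , drop = FALSE]
  items$month <- month_index(items$date, window_start, study_months)

  panel <- items |>
    dplyr::group_by(.data$household_id, .data$month) |>
    dplyr::summarise(produce_items = sum(.data$is_produce),
                     total_items = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cohort[, c("household_id", "age_group", "income_group")],
                     by = "household_id") |>
    dplyr::arrange(.data$household_id, .data$month)
  attr(panel, "dropped_items") <- dropped
  panel
}

#' Weighted monthly produce-share series
#'
#' Per month (and optional demographic group), the item-weighted mean percent
#' produce purchased across households: with weights \eqn{w_i = n_{ij}} (food
#' items) and household shares \eqn{p_i = Y_{ij}/n_{ij}}, the weighted mean
#' \eqn{\sum w_i p_i / \sum w_i} equals the pooled share \eqn{\sum Y / \sum
#' n}. The 95% interval uses a design-based between-household variance that
#' respects the household as the sampling unit,
#' \eqn{\widehat{Var} = \sum w_i^2 (p_i - \bar p)^2 / (\sum w_i)^2},
#' with a normal critical value.
#'
#' @param panel A purchase panel from [build_panel()] or [simulate_panel()].
#' @param grouping `"none"`, `"age"`, or `"income"`.
#' @return A tibble of class `produce_series`: `month`, optional `group`,
#'   `weighted_mean`, `ci_low`, `ci_high` (proportions), `total_items`,
#'   `n_households`.
#' @export
weighted_monthly_series <- function(panel,
                                    grouping = c("none", "age", "income")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(panel) > 0)
  panel <- tibble::as_tibble(panel)
  panel$group <- switch(grouping,
                        none = "all",
                        age = panel$age_group,
                        income = panel$income_group)
  z <- qnorm(0.975)
  out <- panel |>
    dplyr::group_by(.data$group, .data$month) |>
    dplyr::summarise(
      weighted_mean = sum(.data$produce_items) / sum(.data$total_items),
      se = sqrt(sum(.data$total_items^2 *
                      (.data$produce_items / .data$total_items -
                         weighted_mean)^2)) / sum(.data$total_items),
      total_items = sum(.data$total_items),
      n_households = dplyr::n_distinct(.data$household_id),
      .groups = "drop") |>
    dplyr::mutate(ci_low = .data$weighted_mean - z * .data$se,
                  ci_high = .data$weighted_mean + z * .data$se) |>
    dplyr::select("group", "month", "weighted_mean", "ci_low", "ci_high",
                  "total_items", "n_households") |>
    dplyr::arrange(.data$group, .data$month)
  structure(out, grouping = grouping,
            class = c("produce_series", class(out)))
}

#' Grand mean produce share
#'
#' The item-weighted overall proportion of produce among all food items over
#' every household and month — the horizontal reference line in the seasonal
#' figures.
#'
#' @inheritParams weighted_monthly_series
#' @return A single proportion.
#' @export
grand_mean <- function(panel) {
  stopifnot(nrow(panel) > 0)
  sum(panel$produce_items) / sum(panel$total_items)
}
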