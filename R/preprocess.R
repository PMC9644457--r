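#' Exclusion rules for raw transaction items
#'
#' The analysis cohort keeps everyday household food purchases only. The rule
#' set mirrors standard loyalty-card cleaning: drop whole non-food departments
#' (e.g. pharmacy), drop non-food products hiding inside food departments
#' (candy-making supplies, pet food, coupons), drop bulk party items not meant
#' for everyday consumption — produce party trays at or above 1 lb, cheese and
#' cold-cut party trays at or above 2 lb, and beer kegs — and drop every item
#' from households whose head is older than the oldest admissible age group.
#' Weight thresholds are inclusive (`>=`).
#'
#' @param non_food_departments Departments removed outright.
#' @param non_food_item_patterns Regular expressions matched (case-insensitive)
#'   against category and item description within food departments.
#' @param produce_tray_max_lb Produce party trays at/above this weight are
#'   removed (default 1).
#' @param deli_tray_max_lb Cheese/cold-cut party trays at/above this weight
#'   are removed (default 2).
#' @param keg_patterns Patterns identifying keg items.
#' @param max_head_age_label Oldest admissible raw age label; households with
#'   a later label are excluded wholesale.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(non_food_departments = c("pharmacy",
                                                     "health and beauty",
                                                     "floral",
                                                     "general merchandise"),
                            non_food_item_patterns = c("candy making",
                                                       "candy mold",
                                                       "pet food",
                                                       "coupon",
                                                       "gift card"),
                            produce_tray_max_lb = 1,
                            deli_tray_max_lb = 2,
                            keg_patterns = "keg",
                            max_head_age_label = "75-89") {
  stopifnot(produce_tray_max_lb > 0, deli_tray_max_lb > 0)
  structure(list(non_food_departments = tolower(non_food_departments),
                 non_food_item_patterns = tolower(non_food_item_patterns),
                 produce_tray_max_lb = produce_tray_max_lb,
                 deli_tray_max_lb = deli_tray_max_lb,
                 keg_patterns = tolower(keg_patterns),
                 max_head_age_label = max_head_age_label),
            class = "exclusion_rules")
}

#' Classify items as fresh produce
#'
#' An item counts as fresh produce when its department is `produce` and its
#' category is one of the thirteen fresh categories ([produce_categories()]);
#' matching is case-insensitive. Frozen, dried, canned, and juice categories
#' under the produce department are food but not produce.
#'
#' @param items A data frame with `department` and `category` columns.
#' @return The input as a tibble with a logical `is_produce` column added (or
#'   replaced).
#' @examples
#' classify_produce(data.frame(department = "produce", category = "bananas"))
#' @export
classify_produce <- function(items) {
  stopifnot(all(c("department", "category") %in% names(items)))
  items <- tibble::as_tibble(items)
  items$is_produce <- tolower(items$department) == "produce" &
    tolower(items$category) %in% produce_categories()
  items
}

#' Apply the exclusion rules to raw items
#'
#' Removes items in the order: excluded head-of-household age, non-food
#' department, non-food item pattern, keg, produce party tray at/above
#' threshold, deli party tray at/above threshold. Each removed item is
#' attributed to exactly the first rule it matches, so the removal log
#' partitions the removals; trays with a missing weight are retained. The
#' operation is idempotent.
#'
#' @param items Transaction items (must carry `household_id`, `department`,
#'   `category`, `class`, `item_description`, `unit_weight_lb`).
#' @param households Household table with `household_id` and `age_group_raw`.
#' @param rules An [exclusion_rules()] object.
#' @return A tibble of retained items with `is_food = TRUE`; the removal log
#'   (a tibble of rule/count pairs, including a `retained` row) is attached as
#'   attribute `"removal_log"` and printed by [removal_log()].
#' @export
apply_exclusions <- function(items, households, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  if (!("household_id" %in% names(items)) ||
      !("household_id" %in% names(households))) {
    abort("`items` and `households` must share a `household_id` column")
  }
  items <- tibble::as_tibble(items)
  dept <- tolower(items$department)
  cat_lo <- tolower(items$category)
  desc <- tolower(paste(items$category, items$item_description))
  wlb <- items$unit_weight_lb %||% rep(NA_real_, nrow(items))

  ord <- age_levels_raw()
  max_i <- match(rules$max_head_age_label, ord)
  if (is.na(max_i)) max_i <- length(ord) # labels beyond the raw set
  hh_age <- households$age_group_raw[match(items$household_id,
                                           households$household_id)]
  age_i <- match(hh_age, c(ord, "90-99"))
  over_age <- !is.na(age_i) & age_i > max_i

  pat <- paste(rules$non_food_item_patterns, collapse = "|")
  keg <- paste(rules$keg_patterns, collapse = "|")
  is_tray <- grepl("party tray", desc, fixed = TRUE) |
    grepl("party tray", tolower(items$class %||% ""), fixed = TRUE)

  rule <- dplyr::case_when(
    over_age ~ "head_age",
    dept %in% rules$non_food_departments ~ "non_food_department",
    grepl(pat, desc) | grepl(pat, cat_lo) ~ "non_food_pattern",
    grepl(keg, desc) ~ "keg",
    is_tray & dept == "produce" & !is.na(wlb) &
      wlb >= rules$produce_tray_max_lb ~ "produce_tray",
    is_tray & dept != "produce" & !is.na(wlb) &
      wlb >= rules$deli_tray_max_lb ~ "deli_tray",
    .default = "retained")

  log <- dplyr::count(tibble::tibble(rule = factor(
    rule, levels = c("head_age", "non_food_department", "non_food_pattern",
                     "keg", "produce_tray", "deli_tray", "retained"))),
    .data$rule, .drop = FALSE, name = "items")
  kept <- items[rule == "retained", , drop = FALSE]
  kept$is_food <- TRUE
  attr(kept, "removal_log") <- log
  kept
}

#' @rdname apply_exclusions
#' @param cleaned The result of `apply_exclusions()`.
#' @export
removal_log <- function(cleaned) {
  attr(cleaned, "removal_log")
}

#' Restrict households to complete cases
#'
#' The trend models use households with observed age group, income group, and
#' household size; rows missing any of these are dropped. The family flag is
#' descriptive only and does not gate inclusion.
#'
#' @param households Household table.
#' @return Tibble of retained rows; counts of rows missing each field are
#'   attached as attribute `"dropped"`.
#' @export
complete_case_filter <- function(households) {
  households <- tibble::as_tibble(households)
  need <- c("age_group_raw", "income_group_raw", "household_size")
  stopifnot(all(need %in% names(households)))
  miss <- vapply(households[need], function(x) is.na(x), logical(nrow(households)))
  if (nrow(households) == 1L) miss <- matrix(miss, nrow = 1L,
                                             dimnames = list(NULL, need))
  keep <- rowSums(miss) == 0L
  out <- households[keep, , drop = FALSE]
  attr(out, "dropped") <- setNames(colSums(miss),
                                   c("age", "income", "household_size"))
  out
}

#' Month index within the study window
#'
#' Maps calendar dates to the integer study month, 1 for the window's first
#' month and incremented per calendar month.
#'
#' @param date A `Date` vector.
#' @param window_start First day of month 1.
#' @param study_months Optional window length; when given, dates past the
#'   window are an error.
#' @return Integer vector of month indices.
#' @examples
#' month_index(as.Date("2016-12-31"), as.Date("2016-01-01"))  # 12
#' @export
month_index <- function(date, window_start = as.Date("2016-01-01"),
                        study_months = NULL) {
  stopifnot(inherits(date, "Date"), inherits(window_start, "Date"))
  ym <- function(d) as.integer(format(d, "%Y")) * 12L +
    as.integer(format(d, "%m"))
  idx <- ym(date) - ym(window_start) + 1L
  if (any(idx < 1L, na.rm = TRUE) ||
      (!is.null(study_months) && any(idx > study_months, na.rm = TRUE))) {
    abort("date outside the study window")
  }
  idx
}

#' Add collapsed analysis groups to a household table
#'
#' @param households Household table with `age_group_raw`, `income_group_raw`.
#' @return The table with `age_group` and `income_group` columns added.
#' @export
collapse_demographics <- function(households) {
  households <- tibble::as_tibble(households)
  households$age_group <- collapse_age(households$age_group_raw)
  households$income_group <- collapse_income(households$income_group_raw)
  households
}
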