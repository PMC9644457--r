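#' Simulate the household demographics table
#'
#' Draws one row per household: raw age and income groups from the configured
#' marginal shares, a family flag, a household-size category, and a zip code.
#' Missingness is then applied independently per field family at the
#' configured rates (age; income; family flag and size together). The drawn
#' (pre-missingness) age and income labels are retained in the dot-prefixed
#' columns `.age_true` / `.income_true` so the transaction simulator can
#' condition purchasing on a household's actual cell even when the observed
#' field is blanked; downstream analysis code never reads them.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `household_id`, `age_group_raw`,
#'   `income_group_raw`, `family`, `household_size`, `zip`, `.age_true`,
#'   `.income_true`. Missing observed fields are `NA`.
#' @examples
#' hh <- simulate_households(sim_config(n_households = 20, seed = 7))
#' @export
simulate_households <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_households
  with_seed(config$seed * 7L + 1L, {
    age <- sample(age_levels_raw(), n, replace = TRUE,
                  prob = config$age_shares)
    income <- sample(income_levels_raw(), n, replace = TRUE,
                     prob = config$income_shares)
    family <- runif(n) < 0.496
    size <- sample(names(default_household_size_shares()), n, replace = TRUE,
                   prob = default_household_size_shares())
    zip <- sample(sprintf("146%02d", 1:25), n, replace = TRUE)
    miss_age <- runif(n) < config$missing_rates[["age"]]
    miss_inc <- runif(n) < config$missing_rates[["income"]]
    miss_fam <- runif(n) < config$missing_rates[["family"]]

    tibble::tibble(
      household_id = sprintf("H%07d", seq_len(n)),
      age_group_raw = ifelse(miss_age, NA_character_, age),
      income_group_raw = ifelse(miss_inc, NA_character_, income),
      family = ifelse(miss_fam, NA, family),
      household_size = ifelse(miss_fam, NA_character_, size),
      zip = zip,
      .age_true = age,
      .income_true = income)
  })
}

# department/category menu for retained non-produce food items; includes the
# look-alikes the classifier must reject (frozen produce department items,
# sub-threshold deli trays)
nonproduce_menu <- function() {
  tibble::tribble(
    ~department, ~category,            ~class,          ~weight_lo, ~weight_hi, ~prob,
    "grocery",   "cereal",             "breakfast",     NA,         NA,         0.18,
    "grocery",   "pasta",              "dry goods",     NA,         NA,         0.12,
    "dairy",     "yogurt",             "greek yogurt",  NA,         NA,         0.12,
    "dairy",     "milk",               "whole milk",    NA,         NA,         0.10,
    "bakery",    "bread",              "sliced",        NA,         NA,         0.10,
    "meat",      "chicken",            "fresh poultry", NA,         NA,         0.10,
    "frozen",    "frozen meals",       "entree",        NA,         NA,         0.10,
    "produce",   "frozen vegetables",  "frozen",        NA,         NA,         0.05,
    "produce",   "canned fruit",       "canned",        NA,         NA,         0.03,
    "produce",   "juice",              "bottled",       NA,         NA,         0.03,
    "deli",      "cold cuts",          "sliced",        NA,         NA,         0.04,
    "deli",      "cheese party tray",  "party tray",    0.5,        1.9,        0.015,
    "produce",   "produce party tray", "party tray",    0.3,        0.9,        0.015)
}

# removable items that exercise each preprocessing exclusion rule
filter_menu <- function() {
  tibble::tribble(
    ~department,  ~category,            ~class,        ~weight_lo, ~weight_hi,
    "pharmacy",   "medicine",           "otc",         NA,         NA,
    "health and beauty", "shampoo",     "hair care",   NA,         NA,
    "bulk food",  "candy making mold",  "supplies",    NA,         NA,
    "bulk food",  "pet food",           "bulk",        NA,         NA,
    "grocery",    "coupon",             "coupon",      NA,         NA,
    "beer",       "beer keg",           "keg",         55,         58,
    "produce",    "produce party tray", "party tray",  1.0,        3.0,
    "deli",       "cheese party tray",  "party tray",  2.0,        4.0)
}

#' Simulate the transaction-items table
#'
#' For every household and study month, draws a Poisson number of store
#' visits; each visit becomes one transaction with a Poisson number of item
#' lines. A configurable share of items are "removable" kinds that the
#' preprocessing exclusion rules must catch (non-food departments, non-food
#' patterns inside food departments, beer kegs, at-or-above-threshold produce
#' and deli party trays); every other item is a food item which is fresh
#' produce with the cell- and month-specific probability
#' [true_produce_percent()] (a beta-binomial equivalent when the truth's
#' `dispersion` exceeds 1). Retained food items therefore follow the
#' generating mean model exactly. A small share of item lines is emitted twice
#' to exercise unique-item counting.
#'
#' @param households Output of [simulate_households()].
#' @param config The same [sim_config()].
#' @return A tibble with one row per item line: `household_id`,
#'   `transaction_id`, `date`, `store_id`, `department`, `category`, `class`,
#'   `item_description`, `unit_weight_lb`.
#' @export
simulate_transactions <- function(households, config) {
  stopifnot(inherits(config, "sim_config"), nrow(households) > 0)
  age <- households[[".age_true"]] %||% households[["age_group_raw"]]
  income <- households[[".income_true"]] %||% households[["income_group_raw"]]
  if (anyNA(age) || anyNA(income)) {
    abort("households must carry complete `.age_true`/`.income_true` labels")
  }
  cell <- tibble::tibble(household_id = households$household_id,
                         age_group = collapse_age(age),
                         income_group = collapse_income(income))

  with_seed(config$seed * 7L + 2L, {
    hm <- tidyr::expand_grid(household_id = households$household_id,
                             month = seq_len(config$study_months))
    hm$visits <- rpois(nrow(hm), config$visits_per_month)
    hm <- hm[hm$visits > 0L, ]

    trans <- tidyr::uncount(hm, .data$visits)
    trans$transaction_id <- sprintf("T%09d", seq_len(nrow(trans)))
    trans$store_id <- sample.int(config$n_stores, nrow(trans), replace = TRUE)
    trans$date <- month_start(config$window_start, trans$month) +
      sample.int(28L, nrow(trans), replace = TRUE) - 1L
    trans$n_items <- rpois(nrow(trans), config$items_per_visit)
    trans <- trans[trans$n_items > 0L, ]

    items <- tidyr::uncount(trans, .data$n_items)
    # uncount preserves row order, so within-transaction sequence numbers can
    # be laid down without a grouped pass
    items$item_seq <- sequence(trans$n_items)
    items <- dplyr::left_join(items, cell, by = "household_id")
    m <- nrow(items)

    is_removable <- runif(m) < config$filter_share
    p <- true_produce_percent(config$truth, items$age_group,
                              items$income_group, items$month)
    p <- inflate_item_probs(p, items$household_id, items$month,
                            config$truth$dispersion)
    is_produce <- !is_removable & runif(m) < p

    dept <- category <- class <- character(m)
    wlb <- rep(NA_real_, m)

    # removable kinds, uniform over the rule-targeting menu
    fm <- filter_menu()
    k <- sample.int(nrow(fm), sum(is_removable), replace = TRUE)
    dept[is_removable] <- fm$department[k]
    category[is_removable] <- fm$category[k]
    class[is_removable] <- fm$class[k]
    wlb[is_removable] <- draw_weights(fm$weight_lo[k], fm$weight_hi[k])

    # fresh produce items
    category[is_produce] <- sample(produce_categories(), sum(is_produce),
                                   replace = TRUE)
    dept[is_produce] <- "produce"
    class[is_produce] <- "fresh"

    # other food items
    other <- !is_removable & !is_produce
    nm <- nonproduce_menu()
    k <- sample.int(nrow(nm), sum(other), replace = TRUE, prob = nm$prob)
    dept[other] <- nm$department[k]
    category[other] <- nm$category[k]
    class[other] <- nm$class[k]
    wlb[other] <- draw_weights(nm$weight_lo[k], nm$weight_hi[k])

    items$department <- dept
    items$category <- category
    items$class <- class
    items$unit_weight_lb <- wlb
    # distinct items in a transaction always get distinct descriptions, so
    # unique-item counting collapses only literal rescans
    items$item_description <- paste0(items$category, " #", items$item_seq)

    out <- items[, c("household_id", "transaction_id", "date", "store_id",
                     "department", "category", "class", "item_description",
                     "unit_weight_lb")]
    if (config$duplicate_share > 0) {
      dup <- which(runif(nrow(out)) < config$duplicate_share)
      out <- dplyr::arrange(dplyr::bind_rows(out, out[dup, ]),
                            .data$transaction_id, .data$item_description)
    }
    tibble::as_tibble(out)
  })
}

# uniform weights where bounds are given, NA elsewhere
draw_weights <- function(lo, hi) {
  out <- rep(NA_real_, length(lo))
  ok <- !is.na(lo)
  out[ok] <- runif(sum(ok), lo[ok], hi[ok])
  out
}

# first calendar day of study month `month` (1-based) after `start`
month_start <- function(start, month) {
  y <- as.integer(format(start, "%Y"))
  m0 <- as.integer(format(start, "%m")) - 1L + as.integer(month) - 1L
  as.Date(sprintf("%d-%02d-01", y + m0 %/% 12L, m0 %% 12L + 1L))
}

# Beta-binomial option: replace the common item probability with one
# household-month Beta draw so the month total has variance inflation ~
# `dispersion` at typical basket sizes.
inflate_item_probs <- function(p, household_id, month, dispersion) {
  if (dispersion <= 1) return(p)
  key <- paste(household_id, month)
  first <- !duplicated(key)
  n_bar <- mean(tabulate(factor(key)))
  theta <- max((n_bar - dispersion) / (dispersion - 1), 0.5)
  draw <- rbeta(sum(first), p[first] * theta, (1 - p[first]) * theta)
  draw[match(key, key[first])]
}

#' Simulate a household-month purchase panel directly
#'
#' Draws the analysis panel straight from the generating model, without
#' materialising item-level transactions: each household gets a collapsed
#' age-by-income cell, and each household-month a Poisson food-item total
#' `n` and a binomial (or beta-binomial when `dispersion > 1`) produce count
#' `Y` with mean [true_produce_percent()]. Months with a zero item total are
#' dropped, mirroring the missing-timepoint behaviour of real panels. Used
#' for simulation studies where the transaction layer is not under test.
#'
#' @param n_households Number of households.
#' @param truth A [produce_truth()] object.
#' @param study_months Panel length in months.
#' @param mean_items Mean food items per household-month.
#' @param cell_probs Optional 5x6 matrix of cell probabilities; defaults to
#'   the product of the default collapsed age and income shares.
#' @param seed Integer seed.
#' @return A tibble: `household_id`, `month`, `produce_items`, `total_items`,
#'   `age_group`, `income_group`.
#' @export
simulate_panel <- function(n_households, truth = produce_truth(),
                           study_months = truth$study_months,
                           mean_items = 58, cell_probs = NULL, seed = 1L) {
  stopifnot(inherits(truth, "produce_truth"), n_households >= 1,
            mean_items > 0)
  if (is.null(cell_probs)) {
    age_p <- tapply(default_age_shares(), collapse_age(age_levels_raw()), sum)
    inc_p <- tapply(default_income_shares(),
                    collapse_income(income_levels_raw()), sum)
    cell_probs <- outer(age_p[age_levels()], inc_p[income_levels()])
  }
  stopifnot(all(dim(cell_probs) == c(5L, 6L)), abs(sum(cell_probs) - 1) < 1e-8)
  with_seed(seed, {
    cell <- sample.int(30L, n_households, replace = TRUE, prob = c(cell_probs))
    hh <- tibble::tibble(
      household_id = sprintf("H%07d", seq_len(n_households)),
      age_group = age_levels()[(cell - 1L) %% 5L + 1L],
      income_group = income_levels()[(cell - 1L) %/% 5L + 1L])
    panel <- tidyr::expand_grid(hh, month = seq_len(study_months))
    panel$total_items <- rpois(nrow(panel), mean_items)
    panel <- panel[panel$total_items > 0L, ]
    p <- true_produce_percent(truth, panel$age_group, panel$income_group,
                              panel$month)
    if (truth$dispersion > 1) {
      theta <- max((mean_items - truth$dispersion) / (truth$dispersion - 1), 0.5)
      p <- rbeta(nrow(panel), p * theta, (1 - p) * theta)
    }
    panel$produce_items <- rbinom(nrow(panel), panel$total_items, p)
    panel[, c("household_id", "month", "produce_items", "total_items",
              "age_group", "income_group")]
  })
}
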