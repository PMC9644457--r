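# Shared fixtures built in code.

# a small deterministic panel for model tests
small_panel <- function(n = 120, seed = 11, truth = produce_truth()) {
  simulate_panel(n, truth = truth, seed = seed)
}

# hand-written panel with known counts
toy_panel <- function() {
  tibble::tibble(
    household_id = c("A", "A", "B", "B", "C"),
    month = c(1L, 3L, 1L, 4L, 1L),
    produce_items = c(2L, 2L, 6L, 0L, 1L),
    total_items = c(10L, 10L, 20L, 5L, 4L),
    age_group = c("18-24", "18-24", "55-74", "55-74", "35-54"),
    income_group = c("0-14.9K", "0-14.9K", ">=100K", ">=100K", "50-74.9K"))
}

# 20 crafted items covering every exclusion rule plus retained look-alikes
filter_fixture_items <- function() {
  tibble::tibble(
    household_id = c(rep("H1", 18), "H9", "H1"),
    transaction_id = sprintf("T%02d", 1:20),
    date = as.Date("2016-03-05") + 0:19,
    store_id = 1L,
    department = c("pharmacy", "health and beauty", "bulk food", "bulk food",
                   "grocery", "produce", "produce", "deli", "deli", "beer",
                   "produce", "produce", "produce", "produce", "dairy",
                   "grocery", "bakery", "frozen", "produce", "grocery"),
    category = c("medicine", "shampoo", "candy making mold", "pet food",
                 "coupon", "produce party tray", "produce party tray",
                 "cheese party tray", "cheese party tray", "beer keg",
                 "frozen vegetables", "bananas", "berries", "salad leaf",
                 "yogurt", "cereal", "bread", "frozen meals", "citrus",
                 "pasta"),
    class = c("otc", "hair care", "supplies", "bulk", "coupon", "party tray",
              "party tray", "party tray", "party tray", "keg", "frozen",
              "fresh", "fresh", "fresh", "greek yogurt", "breakfast",
              "sliced", "entree", "fresh", "dry goods"),
    item_description = c("medicine #1", "shampoo #1", "candy making mold #1",
                         "pet food #1", "coupon #1", "produce party tray #1",
                         "produce party tray #2", "cheese party tray #1",
                         "cheese party tray #2", "beer keg #1",
                         "frozen vegetables #1", "bananas #1", "berries #1",
                         "salad leaf #1", "yogurt #1", "cereal #1",
                         "bread #1", "frozen meals #1", "citrus #1",
                         "pasta #1"),
    unit_weight_lb = c(NA, NA, NA, NA, NA, 1.0, 0.9, 2.0, 1.9, 58, NA, NA,
                       NA, NA, NA, NA, NA, NA, NA, NA))
}

filter_fixture_households <- function() {
  tibble::tibble(
    household_id = c("H1", "H9"),
    age_group_raw = c("55-74.9", "90-99"),
    income_group_raw = c("50-74.9K", "50-74.9K"),
    family = c(TRUE, FALSE),
    household_size = c("2", "1"))
}
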