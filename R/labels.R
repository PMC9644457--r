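#' Demographic label sets
#'
#' Loyalty-card demographics arrive in nine annual-household-income groups and
#' six head-of-household age groups. For analysis the age groups are collapsed
#' to five (35-44.9 and 45-54.9 merge into 35-54) and the income groups to six
#' (15-19.9K with 20-29.9K, 30-39.9K with 40-49.9K, and the two >=100K groups
#' merge). A further five-level income set matches the census (ACS) household
#' income margins used for representativeness comparisons.
#'
#' @return A character vector of labels, ordered from youngest/lowest upward.
#' @seealso [collapse_age()], [collapse_income()], [collapse_income_acs()]
#' @export
age_levels_raw <- function() {
  c("18-24.9", "25-34.9", "35-44.9", "45-54.9", "55-74.9", "75-89")
}

#' @rdname age_levels_raw
#' @export
age_levels <- function() {
  c("18-24", "25-34", "35-54", "55-74", "75-89")
}

#' @rdname age_levels_raw
#' @export
income_levels_raw <- function() {
  c("0-14.9K", "15-19.9K", "20-29.9K", "30-39.9K", "40-49.9K",
    "50-74.9K", "75-99.9K", "100-124.9K", ">=125K")
}

#' @rdname age_levels_raw
#' @export
income_levels <- function() {
  c("0-14.9K", "15-29.9K", "30-49.9K", "50-74.9K", "75-99.9K", ">=100K")
}

#' @rdname age_levels_raw
#' @export
income_levels_acs <- function() {
  c("0-14.9K", "15-49.9K", "50-74.9K", "75-99.9K", ">=100K")
}

#' Fresh produce categories
#'
#' The thirteen category labels under the produce department that count as
#' fresh produce. Frozen, dried, and canned produce and juices carried under
#' the same department are deliberately absent.
#'
#' @return A character vector of 13 category labels.
#' @export
produce_categories <- function() {
  c("summer fruit", "berries", "grapes", "seasonal/specialty",
    "apples and pears", "salad vegetables", "citrus", "tropical fruit",
    "bananas", "melons", "potatoes and onions", "cooking vegetables",
    "salad leaf")
}

#' Collapse raw demographic labels to analysis groups
#'
#' `collapse_age()` maps the six raw head-of-household age groups onto the five
#' analysis groups (35-44.9 and 45-54.9 both become 35-54). `collapse_income()`
#' maps the nine raw income groups onto six (15-19.9K and 20-29.9K become
#' 15-29.9K; 30-39.9K and 40-49.9K become 30-49.9K; 100-124.9K and >=125K
#' become >=100K). `collapse_income_acs()` further merges 15-29.9K and 30-49.9K
#' into 15-49.9K to align with census income margins.
#'
#' Missing values pass through as `NA`; any other label outside the expected
#' set is an error.
#'
#' @param x Character vector of labels (raw labels for `collapse_age()` and
#'   `collapse_income()`; six-level labels for `collapse_income_acs()`).
#' @return A character vector of collapsed labels, same length as `x`.
#' @examples
#' collapse_age(c("45-54.9", "18-24.9"))
#' collapse_income(c("20-29.9K", ">=125K"))
#' @export
collapse_age <- function(x) {
  map <- c("18-24.9" = "18-24", "25-34.9" = "25-34", "35-44.9" = "35-54",
           "45-54.9" = "35-54", "55-74.9" = "55-74", "75-89" = "75-89")
  collapse_labels(x, map, "age group")
}

#' @rdname collapse_age
#' @export
collapse_income <- function(x) {
  map <- c("0-14.9K" = "0-14.9K", "15-19.9K" = "15-29.9K",
           "20-29.9K" = "15-29.9K", "30-39.9K" = "30-49.9K",
           "40-49.9K" = "30-49.9K", "50-74.9K" = "50-74.9K",
           "75-99.9K" = "75-99.9K", "100-124.9K" = ">=100K",
           ">=125K" = ">=100K")
  collapse_labels(x, map, "income group")
}

#' @rdname collapse_age
#' @export
collapse_income_acs <- function(x) {
  map <- c("0-14.9K" = "0-14.9K", "15-29.9K" = "15-49.9K",
           "30-49.9K" = "15-49.9K", "50-74.9K" = "50-74.9K",
           "75-99.9K" = "75-99.9K", ">=100K" = ">=100K")
  collapse_labels(x, map, "income group")
}

collapse_labels <- function(x, map, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% names(map))
  if (any(bad)) {
    abort(sprintf("unknown %s label(s): %s", what,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  unname(map[x])
}
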