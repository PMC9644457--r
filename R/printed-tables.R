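#' Published loyalty-card cohort marginals
#'
#' Household counts transcribed from the published descriptive tables of the
#' loyalty-card cohort (January 2016 - October 2018, one urban Western New
#' York county), included so the descriptive arithmetic and the census
#' comparison are reproducible without the proprietary microdata. Complete-case
#' denominators differ across the tables because each conditions on a
#' different set of observed fields.
#'
#' * `table1_counts()` — households by head-of-household age group (rows) and
#'   annual household income group (columns); 258,977 households with both
#'   fields observed.
#' * `table2_family_counts()` — households by age group and family flag
#'   (no/yes); 244,515 households.
#' * `table2_size_counts()` — households by age group and household size
#'   (1 to 6+); same denominator.
#' * `table3_income_counts()` — loyalty-card versus 2017 American Community
#'   Survey (ACS) county household counts over the five-level census income
#'   groups (264,059 loyalty vs 300,496 county households).
#' * `table3_age_counts()` — loyalty-card household heads versus the ACS
#'   county *population* by age group (the census does not publish
#'   head-of-household age, so the external margin counts people, not
#'   households; the layout is reproduced as published).
#'
#' @return A tibble of counts; the first column holds row labels.
#' @export
table1_counts <- function() {
  tibble::tribble(
    ~age_group, ~`0-14.9K`, ~`15-29.9K`, ~`30-49.9K`, ~`50-74.9K`, ~`75-99.9K`, ~`>=100K`,
    "18-24",    997,        1054,        1573,        1559,        804,         1280,
    "25-34",    3909,       5021,        7252,        8709,        4625,        7190,
    "35-54",    5105,       8605,        17346,       27166,       14641,       18007,
    "55-74",    3638,       7326,        16667,       26331,       18385,       23015,
    "75-89",    1704,       3675,        7069,        8518,        3856,        3950)
}

#' @rdname table1_counts
#' @export
table2_family_counts <- function() {
  tibble::tribble(
    ~age_group, ~no,    ~yes,
    "18-24",    2258,   2787,
    "25-34",    16937,  14990,
    "35-54",    34919,  51584,
    "55-74",    48919,  43851,
    "75-89",    20154,  8116)
}

#' @rdname table1_counts
#' @export
table2_size_counts <- function() {
  tibble::tribble(
    ~age_group, ~`1`,  ~`2`,  ~`3`,  ~`4`,  ~`5`,  ~`6+`,
    "18-24",    1400,  691,   814,   751,   566,   823,
    "25-34",    10041, 6300,  6045,  3817,  2722,  3002,
    "35-54",    16467, 18653, 20759, 13745, 8897,  7982,
    "55-74",    13236, 22369, 23006, 15785, 9726,  8648,
    "75-89",    3658,  9943,  7814,  3927,  1773,  1155)
}

#' @rdname table1_counts
#' @export
table3_income_counts <- function() {
  tibble::tibble(
    label = income_levels_acs(),
    loyalty = c(16233, 77691, 73276, 42785, 54074),
    acs = c(37056, 100056, 53308, 37354, 72722))
}

#' @rdname table1_counts
#' @export
table3_age_counts <- function() {
  tibble::tibble(
    label = age_levels(),
    loyalty = c(10246, 41048, 97378, 100248, 30215),
    acs_people = c(79001, 103767, 187328, 166797, 52183))
}

#' County coverage of the loyalty-card cohort
#'
#' Percent of county households represented in the loyalty-card income
#' comparison: the loyalty total over the ACS county-household total from
#' [table3_income_counts()].
#'
#' @return A single percent.
#' @export
county_coverage_percent <- function() {
  t3 <- table3_income_counts()
  100 * sum(t3$loyalty) / sum(t3$acs)
}
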