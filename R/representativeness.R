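#' Percentage tables from marginal counts
#'
#' Turns a table of counts into percentages of a row, column, or overall
#' total, rounded half-away-from-zero to the requested number of decimals (the
#' convention of the descriptive tables this mirrors).
#'
#' @param counts A data frame whose first column holds row labels and whose
#'   remaining columns are nonnegative counts.
#' @param axis `"column"` (each count column sums to 100), `"row"` (each row
#'   sums to 100), or `"overall"` (percent of the grand total).
#' @param decimals Decimal places to round to (default 1).
#' @return A tibble of the same shape with counts replaced by percentages.
#' @examples
#' table_percentages(table1_counts(), axis = "column")
#' @export
table_percentages <- function(counts, axis = c("column", "row", "overall"),
                              decimals = 1) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(counts), ncol(counts) >= 2, nrow(counts) >= 1)
  counts <- tibble::as_tibble(counts)
  m <- as.matrix(counts[, -1])
  stopifnot(is.numeric(m), all(m >= 0))
  denom <- switch(axis,
                  column = rep(colSums(m), each = nrow(m)),
                  row = rowSums(m),
                  overall = sum(m))
  if (any(denom == 0)) abort("a zero total leaves cells undefined")
  pct <- round_half_away(100 * m / denom, decimals)
  out <- counts
  out[, -1] <- as.data.frame(pct)
  out
}

#' Round half away from zero
#'
#' The presentation convention of the descriptive tables (`round()` in R
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Collapse six income groups to the census comparison's five
#'
#' Sums the 15-29.9K and 30-49.9K counts into a single 15-49.9K group so
#' loyalty-card income margins line up with the ACS household-income rows.
#'
#' @param counts A tibble with columns `label` (the six collapsed income
#'   groups) and `count`.
#' @return A five-row tibble with the same columns; totals are preserved.
#' @export
collapse_for_acs <- function(counts) {
  stopifnot(all(c("label", "count") %in% names(counts)))
  if (!setequal(counts$label, income_levels())) {
    abort("`counts$label` must be exactly the six collapsed income groups")
  }
  out <- counts |>
    dplyr::mutate(label = collapse_income_acs(.data$label)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out[match(income_levels_acs(), out$label), ]
}

#' Chi-square comparison of two marginal distributions
#'
#' Pearson chi-square on the 2-by-k contingency of internal (loyalty-card)
#' versus external (census) category counts, treating the two sources as
#' independent samples; `df = k - 1`. An expected cell below 5 raises a flag,
#' not a failure.
#'
#' @param internal,external Tibbles with `label` and `count`, same labels in
#'   the same order.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `low_expected_cells`.
#' @examples
#' t3 <- table3_income_counts()
#' chi_square_comparison(
#'   data.frame(label = t3$label, count = t3$loyalty),
#'   data.frame(label = t3$label, count = t3$acs))
#' @export
chi_square_comparison <- function(internal, external) {
  stopifnot(all(c("label", "count") %in% names(internal)),
            all(c("label", "count") %in% names(external)),
            nrow(internal) >= 2)
  if (!identical(as.character(internal$label), as.character(external$label))) {
    abort("`internal` and `external` must share labels in the same order")
  }
  tab <- rbind(internal$count, external$count)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  low <- sum(ct$expected < 5)
  if (low > 0) warn(sprintf("%d expected cell(s) below 5", low))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 low_expected_cells = low)
}
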