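#' Outcome-scale contrasts: baseline percent and annual change
#'
#' `baseline_percent()` reports, per demographic cell in the fitted model, the
#' expected percent produce purchased at the start of the study window: the
#' inverse logit of the cell's linear predictor at `t = 1` with the seasonal
#' terms evaluated at month 1 (January names a calendar instant, so the
#' seasonal dip belongs in the baseline; set `include_seasonal = FALSE` for
#' the seasonally adjusted version). `annual_change()` reports the average
#' linear change in percent produce purchased per year: the cell's per-month
#' logit slope \eqn{\beta_L} plus its interaction terms is assembled by a
#' linear contrast, and rescaled to the outcome as the seasonal-free
#' 12-month difference
#' \eqn{100\,[\mathrm{expit}(\eta_0 + 12\,\mathrm{slope}) -
#' \mathrm{expit}(\eta_0)]} with \eqn{\eta_0} the cell's seasonal-free linear
#' predictor at the window midpoint. Both use delta-method standard errors on
#' the percent scale with the cluster-robust covariance, and normal 95%
#' intervals.
#'
#' @param fit A [fit_produce_gee()] result; must have converged.
#' @param t Month at which the baseline is evaluated (default 1).
#' @param include_seasonal Include the seasonal terms in the baseline
#'   predictor (default `TRUE`).
#' @param level Confidence level.
#' @return A tibble of class `produce_contrasts` with one row per cell:
#'   grouping labels, `quantity` (`"baseline_percent"` or
#'   `"annual_change_percent"`), `estimate`, `ci_low`, `ci_high`, all in
#'   percent.
#' @examples
#' panel <- simulate_panel(150, seed = 3)
#' fit <- fit_produce_gee(panel, grouping = "age")
#' baseline_percent(fit)
#' annual_change(fit)
#' @export
baseline_percent <- function(fit, t = 1, include_seasonal = TRUE,
                             level = 0.95) {
  stopifnot(inherits(fit, "produce_gee"))
  if (!fit$converged) abort("model did not converge; contrasts unavailable")
  cells <- fit_cells(fit)
  xc <- prediction_rows(fit, cells, t = t, seasonal = include_seasonal)
  eta <- drop(xc %*% fit$coefficients)
  pct <- 100 * expit(eta)
  grad <- xc * (100 * expit(eta) * (1 - expit(eta)))
  se <- sqrt(rowSums((grad %*% fit$vcov) * grad))
  finish_contrasts(cells, "baseline_percent", pct, se, level)
}

#' @rdname baseline_percent
#' @export
annual_change <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "produce_gee"))
  if (!fit$converged) abort("model did not converge; contrasts unavailable")
  if (!isTRUE(fit$spec$include_trend)) {
    abort("model has no time trend; annual change is undefined")
  }
  cells <- fit_cells(fit)
  t_mid <- mean(fit$spec$t_range)
  a1 <- prediction_rows(fit, cells, t = t_mid, seasonal = FALSE)
  a2 <- prediction_rows(fit, cells, t = t_mid + 12, seasonal = FALSE)
  p1 <- expit(drop(a1 %*% fit$coefficients))
  p2 <- expit(drop(a2 %*% fit$coefficients))
  est <- 100 * (p2 - p1)
  grad <- 100 * (a2 * (p2 * (1 - p2)) - a1 * (p1 * (1 - p1)))
  se <- sqrt(rowSums((grad %*% fit$vcov) * grad))
  finish_contrasts(cells, "annual_change_percent", est, se, level)
}

# the demographic cells a fit can speak about (groups present at fit time)
fit_cells <- function(fit) {
  lv_age <- fit$spec$age_levels
  lv_inc <- fit$spec$income_levels
  switch(fit$spec$grouping,
         none = tibble::tibble(.rows = 1),
         age = tibble::tibble(age_group = lv_age),
         income = tibble::tibble(income_group = lv_inc),
         age_income = tidyr::expand_grid(age_group = lv_age,
                                         income_group = lv_inc))
}

# design rows for arbitrary cells/months, sharing the fit's formula and
# factor levels so columns line up with the coefficient vector
prediction_rows <- function(fit, cells, t, seasonal) {
  df <- tibble::tibble(
    tt = rep(as.numeric(t), length.out = max(nrow(cells), 1)),
    sin12 = if (fit$spec$include_seasonal) {
      if (seasonal) sin(2 * pi * t / 12) else 0
    } else NULL,
    cos12 = if (fit$spec$include_seasonal) {
      if (seasonal) cos(2 * pi * t / 12) else 0
    } else NULL)
  if ("age_group" %in% names(cells)) {
    if (!all(cells$age_group %in% fit$spec$age_levels)) {
      abort("cell absent from the fitted model")
    }
    df$age_group <- factor(cells$age_group, levels = fit$spec$age_levels)
  }
  if ("income_group" %in% names(cells)) {
    if (!all(cells$income_group %in% fit$spec$income_levels)) {
      abort("cell absent from the fitted model")
    }
    df$income_group <- factor(cells$income_group,
                              levels = fit$spec$income_levels)
  }
  x <- model.matrix(fit$spec$formula, df)
  if (!identical(colnames(x), names(fit$coefficients))) {
    abort("prediction design does not match the fitted coefficients")
  }
  x
}

finish_contrasts <- function(cells, quantity, estimate, se, level) {
  estimate <- unname(estimate)
  se <- unname(se)
  ci <- wald_ci(estimate, se, level)
  out <- dplyr::bind_cols(cells,
                          tibble::tibble(quantity = quantity,
                                         estimate = estimate,
                                         std.error = se,
                                         ci_low = ci$ci_low,
                                         ci_high = ci$ci_high))
  structure(out, class = c("produce_contrasts", class(out)))
}

#' Format an estimate with its interval
#'
#' Renders `estimate (CI low; high)` at one decimal, the house style of the
#' result tables.
#'
#' @param estimate,ci_low,ci_high Numeric vectors in percent.
#' @return A character vector like `"12.2% (CI 11.1; 13.3)"`.
#' @export
format_estimate_ci <- function(estimate, ci_low, ci_high) {
  sprintf("%.1f%% (CI %.1f; %.1f)", estimate, ci_low, ci_high)
}

#' Fitted seasonal curve on the percent scale
#'
#' Evaluates the fitted model's percent produce purchased over a grid of
#' study months for every cell, for overlaying on the observed monthly
#' series.
#'
#' @param fit A `produce_gee` fit.
#' @param months Integer months (default the fitted range).
#' @param include_seasonal Evaluate with the harmonic terms (default) or
#'   seasonal-free.
#' @return A tibble: grouping labels, `month`, `percent`.
#' @export
fitted_curve <- function(fit, months = NULL, include_seasonal = TRUE) {
  stopifnot(inherits(fit, "produce_gee"))
  if (is.null(months)) {
    months <- seq(fit$spec$t_range[1], fit$spec$t_range[2])
  }
  cells <- fit_cells(fit)
  out <- purrr::map_dfr(months, function(t) {
    x <- prediction_rows(fit, cells, t = t, seasonal = include_seasonal)
    dplyr::bind_cols(cells, tibble::tibble(
      month = t, percent = 100 * expit(drop(x %*% fit$coefficients))))
  })
  tibble::as_tibble(out)
}
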