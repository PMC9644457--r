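#' Seasonal trend figure
#'
#' Monthly weighted mean percent produce purchased with 95% error bars, one
#' panel per demographic group, with the fitted harmonic-seasonal curve
#' overlaid and a horizontal grand-mean reference line.
#'
#' @param series A [weighted_monthly_series()] result.
#' @param fit Optional matching [fit_produce_gee()] fit to overlay
#'   (`show_fit = FALSE` or `fit = NULL` renders the data alone).
#' @param grand_mean Optional overall proportion for the reference line.
#' @param show_fit Draw the fitted curve (default `TRUE` when `fit` given).
#' @return A ggplot object.
#' @export
plot_seasonal_trends <- function(series, fit = NULL, grand_mean = NULL,
                                 show_fit = !is.null(fit)) {
  stopifnot(inherits(series, "produce_series"))
  grouping <- attr(series, "grouping")
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$month,
                                            y = 100 * .data$weighted_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$ci_low,
                                        ymax = 100 * .data$ci_high),
                           width = 0.4, colour = "grey55") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Study month", y = "Percent produce purchased") +
    ggplot2::theme_bw()
  if (grouping != "none") {
    p <- p + ggplot2::facet_wrap(~group)
  }
  if (!is.null(grand_mean)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * grand_mean,
                                 linetype = "dashed")
  }
  if (show_fit && !is.null(fit)) {
    if (!identical(fit_grouping_label(fit), grouping)) {
      abort("`fit` grouping does not match the series grouping")
    }
    curve <- fitted_curve(fit)
    curve$group <- switch(grouping,
                          none = "all",
                          age = curve$age_group,
                          income = curve$income_group)
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$month,
                                             y = .data$percent),
                                colour = "steelblue")
  }
  p
}

fit_grouping_label <- function(fit) {
  switch(fit$spec$grouping, age_income = "age_income", fit$spec$grouping)
}

#' Annual rate-of-change figure
#'
#' Point-and-interval chart of the annual change in percent produce purchased,
#' one point per demographic cell (age-by-income fits show income on the axis,
#' panelled by age group).
#'
#' @param contrasts An [annual_change()] result.
#' @return A ggplot object.
#' @export
plot_annual_change <- function(contrasts) {
  stopifnot(inherits(contrasts, "produce_contrasts"))
  if (!all(contrasts$quantity == "annual_change_percent")) {
    abort("`contrasts` must hold annual_change_percent rows")
  }
  has_age <- "age_group" %in% names(contrasts)
  has_inc <- "income_group" %in% names(contrasts)
  xvar <- if (has_inc) "income_group" else if (has_age) "age_group" else NULL
  if (is.null(xvar)) abort("contrasts carry no demographic cells to plot")
  d <- contrasts
  d[[xvar]] <- factor(d[[xvar]], levels = if (has_inc) income_levels()
                      else age_levels())
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = gsub("_", " ", xvar),
                  y = "Annual change in percent produce purchased") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (has_age && has_inc) {
    p <- p + ggplot2::facet_wrap(~age_group)
  }
  p
}

#' @export
autoplot.produce_series <- function(object, ...) {
  plot_seasonal_trends(object, ...)
}

#' @export
autoplot.produce_contrasts <- function(object, ...) {
  if (all(object$quantity == "annual_change_percent")) {
    return(plot_annual_change(object))
  }
  has_inc <- "income_group" %in% names(object)
  xvar <- if (has_inc) "income_group" else "age_group"
  d <- object
  d[[xvar]] <- factor(d[[xvar]], levels = if (has_inc) income_levels()
                      else age_levels())
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = gsub("_", " ", xvar),
                  y = "Baseline percent produce purchased") +
    ggplot2::theme_bw()
  if (has_inc && "age_group" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~age_group)
  }
  p
}
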