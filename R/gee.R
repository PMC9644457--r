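#' Design matrix for the seasonal-trend model
#'
#' One row per panel row: an intercept, harmonic seasonal terms
#' \eqn{\sin(2\pi t/12)} and \eqn{\cos(2\pi t/12)}, linear time `t` (the
#' study-month index), treatment-coded demographic indicators against the
#' youngest/lowest reference levels (18-24, 0-14.9K), and the group-by-time
#' interactions. The `age_income` specification carries the full three-way
#' age-by-income-by-time expansion so every cell has its own intercept and
#' slope. Column order is fixed by the stored formula and factor levels.
#'
#' @param panel A purchase panel (`produce_items`, `total_items`, `month`,
#'   and the grouping columns it needs).
#' @param grouping `"none"`, `"age"`, `"income"`, or `"age_income"`.
#' @param include_seasonal Include the harmonic pair (default `TRUE`).
#' @param include_trend Include the linear time term and its group
#'   interactions (default `TRUE`); with `grouping = "none"` and both flags
#'   off the design is intercept-only.
#' @return A list: `x` (design matrix), `y` (produce counts), `n` (food-item
#'   totals), `cluster` (household ids), and the `spec` used.
#' @export
build_design <- function(panel,
                         grouping = c("none", "age", "income", "age_income"),
                         include_seasonal = TRUE, include_trend = TRUE) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("produce_items", "total_items", "month") %in% names(panel)),
            all(panel$total_items > 0),
            all(panel$produce_items >= 0),
            all(panel$produce_items <= panel$total_items))
  df <- design_frame(panel, include_seasonal)
  lv_age <- lv_inc <- NULL
  if (grouping %in% c("age", "age_income")) {
    check_levels(panel$age_group, age_levels(), "age_group")
    lv_age <- age_levels()[age_levels() %in% unique(panel$age_group)]
    df$age_group <- factor(panel$age_group, levels = lv_age)
  }
  if (grouping %in% c("income", "age_income")) {
    check_levels(panel$income_group, income_levels(), "income_group")
    lv_inc <- income_levels()[income_levels() %in% unique(panel$income_group)]
    df$income_group <- factor(panel$income_group, levels = lv_inc)
  }
  fml <- design_formula(grouping, include_seasonal, include_trend)
  x <- model.matrix(fml, df)
  list(x = x, y = as.numeric(panel$produce_items),
       n = as.numeric(panel$total_items),
       cluster = as.character(panel$household_id),
       spec = list(grouping = grouping, include_seasonal = include_seasonal,
                   include_trend = include_trend,
                   age_levels = lv_age, income_levels = lv_inc,
                   formula = fml, t_range = range(panel$month)))
}

design_frame <- function(panel, include_seasonal) {
  tibble::tibble(
    tt = as.numeric(panel$month),
    sin12 = if (include_seasonal) sin(2 * pi * panel$month / 12) else NULL,
    cos12 = if (include_seasonal) cos(2 * pi * panel$month / 12) else NULL)
}

design_formula <- function(grouping, include_seasonal, include_trend) {
  seas <- if (include_seasonal) c("sin12", "cos12") else character()
  grp <- if (include_trend) {
    switch(grouping,
           none = "tt",
           age = "age_group * tt",
           income = "income_group * tt",
           age_income = "age_group * income_group * tt")
  } else {
    switch(grouping,
           none = character(),
           age = "age_group",
           income = "income_group",
           age_income = "age_group * income_group")
  }
  rhs <- paste(c(seas, grp), collapse = " + ")
  stats::as.formula(paste("~", if (nzchar(rhs)) rhs else "1"))
}

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0 || anyNA(x)) {
    abort(sprintf("`%s` contains labels outside the model's levels: %s",
                  what, paste(bad, collapse = ", ")))
  }
}

#' Fit the seasonal-trend model by working-independence GEE
#'
#' Estimates the marginal logit model for the monthly produce share
#' \deqn{logit\,E(Y_{ij}/n_{ij}) = \beta_0 + \beta_{S1}\sin(2\pi t_{ij}/12) +
#'   \beta_{S2}\cos(2\pi t_{ij}/12) + \beta_L t_{ij} + \beta_X X_i +
#'   \beta_{XL} X_i t_{ij}}
#' by generalized estimating equations with a working-independence
#' correlation. Under working independence the estimating equations coincide
#' with the weighted-logistic normal equations (weights \eqn{n_{ij}},
#' outcomes \eqn{Y_{ij}/n_{ij}}), solved here by iteratively reweighted least
#' squares: convergence when the relative coefficient change falls below
#' `tol`, capped at `max_iter` iterations. Inference uses the cluster-robust
#' empirical sandwich covariance with households as clusters (see
#' [sandwich_covariance()]); no small-sample correction is applied.
#'
#' Complete separation (fitted shares collapsing to 0 or 1) is flagged via
#' the `separation` field and `converged = FALSE`, with the partial fit
#' returned.
#'
#' @inheritParams build_design
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `produce_gee` with elements `coefficients`,
#'   `vcov` (robust), `vcov_model` (model-based), `n_clusters`, `n_obs`,
#'   `iterations`, `converged`, `separation`, and the design pieces needed to
#'   form contrasts.
#' @seealso [baseline_percent()], [annual_change()], [tidy.produce_gee()]
#' @export
fit_produce_gee <- function(panel,
                            grouping = c("none", "age", "income", "age_income"),
                            include_seasonal = TRUE, include_trend = TRUE,
                            tol = 1e-8, max_iter = 100L) {
  grouping <- match.arg(grouping)
  d <- build_design(panel, grouping, include_seasonal, include_trend)
  x <- d$x
  y <- d$y
  n <- d$n
  p <- ncol(x)
  if (qr(x)$rank < p) abort("design matrix has collinear columns")

  beta <- c(logit((sum(y) + 0.5) / (sum(n) + 1)), rep(0, p - 1))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- expit(eta)
    if (any(pmin(mu, 1 - mu) < 1e-10) || max(abs(beta)) > 30) {
      separation <- TRUE
      warn("possible separation: fitted shares at the boundary")
      break
    }
    w <- n * mu * (1 - mu)
    z <- eta + (y / n - mu) / (mu * (1 - mu))
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(x * sw), z * sw)
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(x)

  mu <- expit(drop(x %*% beta))
  a <- crossprod(x * sqrt(n * mu * (1 - mu)))          # model-based information
  a_inv <- tryCatch(solve(a), error = function(e) {
    abort("model-based information is singular; cannot form covariance")
  })
  vc <- cluster_sandwich(x, y, n, mu, d$cluster, a_inv)

  structure(list(coefficients = beta,
                 vcov = vc, vcov_model = a_inv,
                 n_clusters = length(unique(d$cluster)),
                 n_obs = length(y),
                 iterations = iter, converged = converged,
                 separation = separation,
                 spec = d$spec,
                 design = d),
            class = "produce_gee")
}

cluster_sandwich <- function(x, y, n, mu, cluster, a_inv) {
  s <- x * (y - n * mu)                 # per-row score contributions
  sc <- rowsum(s, cluster)              # summed within household
  b <- crossprod(sc)
  vc <- a_inv %*% b %*% a_inv
  (vc + t(vc)) / 2
}

#' Cluster-robust sandwich covariance
#'
#' Recomputes the empirical sandwich \eqn{A^{-1} B A^{-1}} for a fitted
#' model: \eqn{A} is the model-based binomial information
#' \eqn{X^\top W X} with \eqn{W = n\,\mu(1-\mu)}, and \eqn{B} sums, over
#' household clusters, the outer products of summed score contributions
#' \eqn{x_{ij}(Y_{ij} - n_{ij}\mu_{ij})}. Consistent under arbitrary
#' within-household correlation.
#'
#' @param fit A `produce_gee` fit.
#' @return A symmetric positive semi-definite matrix.
#' @export
sandwich_covariance <- function(fit) {
  stopifnot(inherits(fit, "produce_gee"))
  d <- fit$design
  mu <- expit(drop(d$x %*% fit$coefficients))
  a_inv <- solve(crossprod(d$x * sqrt(d$n * mu * (1 - mu))))
  cluster_sandwich(d$x, d$y, d$n, mu, d$cluster, a_inv)
}

#' Normal-theory Wald interval
#'
#' @param estimate,se Numeric vectors (recycled); `se` must be nonnegative.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `estimate`, `ci_low`, `ci_high`.
#' @examples
#' wald_ci(12.2, 0.561)
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (any(se < 0, na.rm = TRUE)) abort("`se` must be nonnegative")
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(estimate = estimate,
                 ci_low = estimate - z * se,
                 ci_high = estimate + z * se)
}

#' @export
print.produce_gee <- function(x, ...) {
  cat(sprintf(
    "Working-independence GEE fit (%s grouping)\n%d household clusters, %d household-months, %d terms\nconverged: %s after %d iterations%s\n",
    x$spec$grouping, x$n_clusters, x$n_obs, length(x$coefficients),
    x$converged, x$iterations,
    if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Tidy a fitted seasonal-trend model
#'
#' @param x A `produce_gee` fit.
#' @param conf.int Add robust Wald confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error` (cluster-robust), `statistic`, `p.value`, and optionally
#'   `conf.low`/`conf.high`.
#' @export
tidy.produce_gee <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        std.error = unname(se),
                        statistic = estimate / std.error,
                        p.value = 2 * stats::pnorm(-abs(statistic)))
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @rdname tidy.produce_gee
#' @export
glance.produce_gee <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
                 n_terms = length(x$coefficients),
                 iterations = x$iterations, converged = x$converged,
                 separation = x$separation)
}
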