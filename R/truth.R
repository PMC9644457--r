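#' Generating model for the monthly produce share
#'
#' The synthetic cohort purchases produce according to a logit-linear mean:
#' for a household in age-by-income cell \eqn{c} in study month \eqn{t},
#' \deqn{logit(p_{ct}) = \alpha_c + \beta_{S1}\sin(2\pi t/12) +
#'       \beta_{S2}\cos(2\pi t/12) + \gamma_c t,}
#' the same harmonic-seasonal plus linear-trend structure the trend model
#' estimates. The truth object is parameterised on the outcome scale, which is
#' what domain calibration targets are stated in:
#'
#' * `baseline_matrix` — percent produce purchased in the first study month
#'   (January, seasonal term included), one value per age-by-income cell.
#'   Defaults span 12.2% (youngest age, lowest income) to 19.3% (oldest,
#'   highest), rising with income within the older age groups and most varied
#'   in the youngest.
#' * `annual_change_matrix` — the true 12-month change in percent produce
#'   purchased, measured seasonal-free at the study midpoint. Defaults are
#'   steepest for the youngest households (1.42 down to 0.69 percent/year
#'   across income) and essentially flat (0.03-0.05) for the oldest. The
#'   per-month logit slope \eqn{\gamma_c} is solved from this target by
#'   root-finding, and \eqn{\alpha_c} is then anchored so the January month-1
#'   percent equals the baseline entry.
#' * `seasonal_sin`, `seasonal_cos` — harmonic coefficients on the logit
#'   scale. Defaults (0.045, -0.045\eqn{\sqrt{3}}) give amplitude 0.09, i.e. a
#'   peak-to-trough swing of about 2.5 percentage points at a 17% share,
#'   peaking in May.
#' * `dispersion` — variance-inflation factor for item-level draws; 1 gives
#'   exact binomial sampling, values above 1 switch to a beta-binomial with
#'   that month-level variance inflation.
#'
#' @param baseline_matrix 5x6 numeric matrix (age groups by income groups) of
#'   month-1 percent produce purchased, in percent.
#' @param annual_change_matrix 5x6 numeric matrix of true annual change in
#'   percent produce purchased, in percent per year.
#' @param seasonal_sin,seasonal_cos Harmonic coefficients, logit scale.
#' @param dispersion Item-level variance inflation factor, >= 1.
#' @param study_months Number of study months (sets the midpoint at which the
#'   annual change is anchored).
#' @return An object of class `produce_truth`: a list with the inputs plus the
#'   implied logit-scale `intercept_matrix` and per-month `slope_matrix`.
#' @examples
#' truth <- produce_truth()
#' true_produce_percent(truth, "75-89", ">=100K", month = 1)  # 19.3
#' @export
produce_truth <- function(baseline_matrix = default_baseline_matrix(),
                          annual_change_matrix = default_annual_change_matrix(),
                          seasonal_sin = 0.045,
                          seasonal_cos = -0.045 * sqrt(3),
                          dispersion = 1,
                          study_months = 33) {
  stopifnot(is.matrix(baseline_matrix), is.matrix(annual_change_matrix),
            all(dim(baseline_matrix) == c(5L, 6L)),
            all(dim(annual_change_matrix) == c(5L, 6L)),
            all(is.finite(baseline_matrix)), all(is.finite(annual_change_matrix)),
            all(baseline_matrix > 0), all(baseline_matrix < 100),
            is.finite(seasonal_sin), is.finite(seasonal_cos),
            is.finite(dispersion), dispersion >= 1, study_months >= 1)
  dimnames(baseline_matrix) <- dimnames(annual_change_matrix) <-
    list(age_levels(), income_levels())
  t_mid <- (1 + study_months) / 2
  seas1 <- seasonal_sin * sin(2 * pi / 12) + seasonal_cos * cos(2 * pi / 12)

  slope <- matrix(NA_real_, 5, 6, dimnames = dimnames(baseline_matrix))
  for (i in seq_len(5)) {
    for (j in seq_len(6)) {
      slope[i, j] <- solve_monthly_slope(baseline_matrix[i, j] / 100,
                                         annual_change_matrix[i, j] / 100,
                                         seas1, t_mid)
    }
  }
  intercept <- logit(baseline_matrix / 100) - seas1 - slope # month-1 anchor

  structure(list(baseline_matrix = baseline_matrix,
                 annual_change_matrix = annual_change_matrix,
                 seasonal_sin = seasonal_sin, seasonal_cos = seasonal_cos,
                 dispersion = dispersion, study_months = study_months,
                 intercept_matrix = intercept, slope_matrix = slope),
            class = "produce_truth")
}

# Per-month logit slope whose seasonal-free 12-month difference at the study
# midpoint equals `annual` (both on the proportion scale).
solve_monthly_slope <- function(p1, annual, seas1, t_mid) {
  if (annual == 0) return(0)
  f <- function(s) {
    eta0 <- logit(p1) - seas1 - s + s * t_mid # intercept + s * t_mid
    (expit(eta0 + 12 * s) - expit(eta0)) - annual
  }
  uniroot(f, interval = c(-0.2, 0.2), tol = 1e-12)$root
}

#' @rdname produce_truth
#' @export
default_baseline_matrix <- function() {
  m <- rbind(
    "18-24" = c(12.2, 12.9, 13.4, 13.1, 13.7, 14.1),
    "25-34" = c(14.9, 15.1, 15.4, 15.7, 16.0, 16.4),
    "35-54" = c(14.2, 14.6, 15.1, 15.6, 16.2, 16.8),
    "55-74" = c(14.6, 15.1, 15.8, 16.6, 17.7, 18.7),
    "75-89" = c(14.1, 14.9, 15.9, 17.0, 18.3, 19.3))
  colnames(m) <- income_levels()
  m
}

#' @rdname produce_truth
#' @export
default_annual_change_matrix <- function() {
  m <- rbind(
    "18-24" = c(1.42, 1.30, 1.15, 1.00, 0.85, 0.69),
    "25-34" = c(0.45, 0.45, 0.45, 0.45, 0.45, 0.40),
    "35-54" = c(0.40, 0.40, 0.38, 0.35, 0.33, 0.30),
    "55-74" = c(0.28, 0.26, 0.24, 0.22, 0.20, 0.18),
    "75-89" = c(0.05, 0.05, 0.04, 0.03, 0.03, 0.03))
  colnames(m) <- income_levels()
  m
}

#' True monthly produce share under the generating model
#'
#' Evaluates the generating mean: the inverse logit of the cell intercept plus
#' harmonic seasonal terms plus the per-month trend.
#'
#' @param truth A [produce_truth()] object.
#' @param age_group,income_group Collapsed cell labels (vectors recycle).
#' @param month Study month index, 1 = first study month; `month >= 1`.
#' @return Numeric vector of proportions in (0, 1).
#' @export
true_produce_percent <- function(truth, age_group, income_group, month) {
  stopifnot(inherits(truth, "produce_truth"), all(month >= 1))
  n <- max(length(age_group), length(income_group), length(month))
  age_group <- rep_len(as.character(age_group), n)
  income_group <- rep_len(as.character(income_group), n)
  month <- rep_len(month, n)
  ai <- match(age_group, age_levels())
  ii <- match(income_group, income_levels())
  if (anyNA(ai) || anyNA(ii)) {
    abort("unknown age/income cell label in `true_produce_percent()`")
  }
  idx <- cbind(ai, ii)
  eta <- truth$intercept_matrix[idx] +
    truth$seasonal_sin * sin(2 * pi * month / 12) +
    truth$seasonal_cos * cos(2 * pi * month / 12) +
    truth$slope_matrix[idx] * month
  expit(eta)
}
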