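# Power-model dose proportionality with the Smith acceptance-range
# criterion: ln(Y) = alpha + beta * ln(dose); proportionality is
# concluded when the 90% CI for beta lies inside
# (1 + ln(theta_L)/ln(R), 1 + ln(theta_H)/ln(R)), R being the ratio of
# the highest to the lowest dose.

#' Fit the power model to individual exposure data
#'
#' Ordinary least squares of `ln(Y)` on `ln(dose)`; the confidence
#' interval uses the t distribution with n - 2 degrees of freedom.
#'
#' @param dose Doses, mg (one per subject; at least two distinct levels).
#' @param y Positive exposure values (e.g. Cmax or AUC), same length.
#' @param parameter_name Label carried into the result.
#' @param ci_level Two-sided confidence level for the slope (default 0.90).
#' @return An object of class `power_model_fit` with fields
#'   `parameter_name`, `alpha`, `beta`, `beta_se`, `ci` (low, high),
#'   `ci_level`, `n_obs`, `dose_range`.
#' @export
fit_power_model <- function(dose, y, parameter_name = "", ci_level = 0.90) {
  keep <- !is.na(y) & !is.na(dose)
  dose <- dose[keep]; y <- y[keep]
  if (length(y) < 3) stop("need >= 3 (dose, Y) pairs")
  if (length(unique(dose)) < 2)
    stop("rank deficiency: need >= 2 distinct dose levels")
  if (any(y <= 0) || any(dose <= 0))
    stop("doses and exposures must be strictly positive")
  f <- .loglin_fit(log(dose), log(y))
  tcrit <- qt(1 - (1 - ci_level) / 2, df = f$n - 2)
  structure(list(parameter_name = parameter_name, alpha = f$intercept,
                 beta = f$slope, beta_se = f$se_slope,
                 ci = c(f$slope - tcrit * f$se_slope,
                        f$slope + tcrit * f$se_slope),
                 ci_level = ci_level, n_obs = f$n,
                 dose_range = range(dose)),
            class = "power_model_fit")
}

#' Fit the power-model slope from group geometric means
#'
#' Weighted least squares of `ln(geometric mean)` on `ln(dose)` with the
#' group sizes as weights.  Because dose is constant within a group,
#' this reproduces the individual-level OLS point estimate exactly; the
#' confidence interval, which needs individual residuals, is reported as
#' unavailable (`NA`).
#'
#' @param dose Dose levels, mg (>= 3 groups).
#' @param geomean Group geometric means of the exposure parameter.
#' @param group_n Group sizes (weights).
#' @param parameter_name Label carried into the result.
#' @return A `power_model_fit` with `ci = c(NA, NA)`.
#' @export
fit_power_model_from_summaries <- function(dose, geomean, group_n,
                                           parameter_name = "") {
  if (length(dose) != length(geomean) || length(dose) != length(group_n))
    stop("dose, geomean and group_n must have equal length")
  if (length(dose) < 3) stop("need >= 3 dose groups")
  if (any(geomean <= 0)) stop("geometric means must be positive")
  if (any(group_n < 1)) stop("group sizes must be >= 1")
  fit <- lm(log(geomean) ~ log(dose), weights = group_n)
  structure(list(parameter_name = parameter_name,
                 alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
                 beta_se = NA_real_, ci = c(NA_real_, NA_real_),
                 ci_level = NA_real_, n_obs = length(dose),
                 dose_range = range(dose)),
            class = "power_model_fit")
}

#' @export
print.power_model_fit <- function(x, ...) {
  cat(sprintf("<power_model_fit> %s: beta = %.4f", x$parameter_name, x$beta))
  if (!is.na(x$ci[1]))
    cat(sprintf(", %g%% CI (%.4f, %.4f)", 100 * x$ci_level, x$ci[1], x$ci[2]))
  cat(sprintf(", n = %d\n", x$n_obs))
  invisible(x)
}

#' Smith acceptance range for the proportionality slope
#'
#' `low = 1 + ln(theta_l)/ln(r)`, `high = 1 + ln(theta_h)/ln(r)` — the
#' bioequivalence limits rescaled by the log of the dose ratio `r`.
#'
#' @param theta_l Lower proportionality limit, in (0, 1); default 0.8.
#' @param theta_h Upper limit, > 1; default 1.25.
#' @param r Ratio of highest to lowest dose (> 1).
#' @return An object of class `acceptance_range` with `low` and `high`.
#' @export
#' @examples
#' acceptance_range(r = 45) # (0.94, 1.06) at 2 d.p.
acceptance_range <- function(theta_l = 0.8, theta_h = 1.25, r) {
  if (!(theta_l > 0 && theta_l < 1 && theta_h > 1))
    stop("need 0 < theta_l < 1 < theta_h")
  if (r <= 1) stop("dose ratio r must be > 1")
  structure(list(theta_l = theta_l, theta_h = theta_h, r = r,
                 low = 1 + log(theta_l) / log(r),
                 high = 1 + log(theta_h) / log(r)),
            class = "acceptance_range")
}

#' Dose-proportionality verdict from a slope CI and an acceptance range
#'
#' Three-way taxonomy: CI contained in the range -> `"proportional"`;
#' CI disjoint from the range -> `"nonproportional"`; any other overlap
#' -> `"inconclusive"` (the rationale notes when the CI is wider than
#' and covers the whole range, the typical small-n wide-dose-range
#' outcome).
#'
#' @param fit A `power_model_fit` with a finite CI.
#' @param range An [acceptance_range()].
#' @return An object of class `proportionality_verdict`: list with
#'   `verdict` and `rationale`.
#' @export
assess_proportionality <- function(fit, range) {
  ci <- fit$ci
  if (any(is.na(ci))) stop("fit has no confidence interval")
  lab <- sprintf("CI (%.2f, %.2f) vs acceptance range (%.2f, %.2f)",
                 ci[1], ci[2], range$low, range$high)
  if (ci[1] >= range$low && ci[2] <= range$high) {
    v <- "proportional"
    why <- paste0("CI contained within the acceptance range; ", lab)
  } else if (ci[2] < range$low || ci[1] > range$high) {
    v <- "nonproportional"
    why <- paste0("CI disjoint from the acceptance range; ", lab)
  } else {
    v <- "inconclusive"
    why <- if (ci[1] <= range$low && ci[2] >= range$high)
      paste0("CI wider than and covering the acceptance range; ", lab)
    else paste0("CI partially overlaps the acceptance range; ", lab)
  }
  structure(list(verdict = v, rationale = why),
            class = "proportionality_verdict")
}

#' Fold change across the dose range
#'
#' Ratio of the exposure geometric mean at the highest dose to that at
#' the lowest, reported next to the dose fold change.
#'
#' @param dose Dose levels, mg (>= 2).
#' @param geomean Positive geometric means, one per dose.
#' @return List with `parameter_fold` and `dose_fold`.
#' @export
fold_range_ratio <- function(dose, geomean) {
  if (length(dose) < 2) stop("need >= 2 dose levels")
  if (any(geomean <= 0)) stop("geometric means must be positive")
  i_lo <- which.min(dose); i_hi <- which.max(dose)
  list(parameter_fold = geomean[i_hi] / geomean[i_lo],
       dose_fold = dose[i_hi] / dose[i_lo])
}
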