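# Standard non-compartmental analysis.
#
# Conventions: Cmax/Tmax are the observed maximum (ties -> earliest
# time); AUC0-t by linear-up/log-down trapezoid to the last measurable
# concentration; lambda_z by log-linear least squares over the
# best-fit terminal window (maximum adjusted R^2 over all >=3-point
# suffixes of the post-Tmax points, Cmax excluded); AUC0-inf adds
# Clast/lambda_z; T1/2 = ln(2)/lambda_z; CL/F = dose/AUC0-inf.

.prepared <- function(profile) {
  if (is.null(attr(profile, "blq_policy"))) blq_policy(profile) else profile
}

#' Maximum observed concentration and its time
#'
#' @param profile A [concentration_profile()] (BLQ policy is applied if
#'   it has not been already).
#' @return A list with elements `cmax` (ng/mL) and `tmax` (h).  Ties are
#'   broken by the earliest time.
#' @export
compute_cmax_tmax <- function(profile) {
  p <- .prepared(profile)
  i <- which.max(p$analysis_conc)  # first index at the max -> earliest time
  list(cmax = p$analysis_conc[i], tmax = p$analysis_time_h[i])
}

# Shared segment-wise trapezoid on bare vectors; log rule only on
# strictly decreasing segments with both endpoints > 0.
.auc_segments <- function(time, conc, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  dt <- diff(time)
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(lin)
  use_log <- c2 < c1 & c2 > 0 & c1 > 0
  lg <- lin
  lg[use_log] <- (c1[use_log] - c2[use_log]) /
    log(c1[use_log] / c2[use_log]) * dt[use_log]
  lg
}

#' Area under the curve by the linear-up/log-down trapezoid rule
#'
#' Each segment uses the linear trapezoid when the concentration is
#' non-decreasing or either endpoint is zero, and the logarithmic
#' trapezoid `(C1 - C2) / ln(C1/C2) * dt` when strictly decreasing with
#' both endpoints positive.
#'
#' @param profile A [concentration_profile()] or a prepared one.
#' @param t_end Upper limit of integration; defaults to the last
#'   measurable time.  Must be at most that time; if it falls strictly
#'   inside a segment the partial segment is interpolated per the same
#'   rule.
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return AUC from 0 (first sample) to `t_end`, in h·ng/mL.
#' @export
auc_linuplogdown <- function(profile, t_end = NULL,
                             method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  p <- .prepared(profile)
  time <- p$analysis_time_h; conc <- p$analysis_conc
  if (length(time) < 2) stop("insufficient data: need >= 2 quantified points")
  if (is.null(t_end)) t_end <- time[length(time)]
  if (t_end > time[length(time)] + 1e-12)
    stop("t_end must not exceed the last quantified time")
  keep <- time <= t_end + 1e-12
  time_k <- time[keep]; conc_k <- conc[keep]
  auc <- sum(.auc_segments(time_k, conc_k, method))
  # partial final segment when t_end falls between samples
  t_last <- time_k[length(time_k)]
  if (t_end > t_last + 1e-12) {
    i <- max(which(keep))
    c1 <- conc[i]; c2 <- conc[i + 1]; t1 <- time[i]; t2 <- time[i + 1]
    if (c2 < c1 && c1 > 0 && c2 > 0) {
      k <- log(c1 / c2) / (t2 - t1)
      auc <- auc + c1 * (1 - exp(-k * (t_end - t1))) / k
    } else {
      ce <- c1 + (c2 - c1) * (t_end - t1) / (t2 - t1)
      auc <- auc + (c1 + ce) / 2 * (t_end - t1)
    }
  }
  auc
}

# Fast closed-form simple linear regression of y on x, with adjusted R^2.
.loglin_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  sse <- sum(res^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  r2_adj <- if (is.na(r2) || n <= 2) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 2)
  se_slope <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, r2_adj = r2_adj,
       se_slope = se_slope, n = n)
}

#' Terminal elimination rate by best-fit log-linear regression
#'
#' Candidate windows are every suffix (>= 3 points) of the quantified
#' points strictly after Tmax (the Cmax point itself is excluded).  The
#' window with the largest adjusted R^2 of `ln(C)` on `t` wins; exact
#' ties go to the window with more points.  `lambda_z` is the negated
#' slope and must be positive.
#'
#' @param profile A [concentration_profile()].
#' @param manual_window Optional `c(t_start, t_end)` overriding the
#'   automatic search; all quantified post-Tmax points inside the window
#'   are used.
#' @return A list: `lambda_z` (1/h, `NA` when undefined), `r2_adj`,
#'   `n_points`, `window` (`c(t_first, t_last)`), and `flag` (`"ok"`,
#'   `"insufficient points"`, or `"no terminal decline"`).
#' @export
fit_lambda_z <- function(profile, manual_window = NULL) {
  p <- .prepared(profile)
  mx <- compute_cmax_tmax(p)
  t_all <- p$analysis_time_h; c_all <- p$analysis_conc
  elig <- t_all > mx$tmax & c_all > 0
  te <- t_all[elig]; ce <- c_all[elig]
  none <- list(lambda_z = NA_real_, r2_adj = NA_real_, n_points = 0L,
               window = c(NA_real_, NA_real_), flag = "insufficient points")
  if (!is.null(manual_window)) {
    inw <- te >= manual_window[1] & te <= manual_window[2]
    if (sum(inw) < 3) return(none)
    f <- .loglin_fit(te[inw], log(ce[inw]))
    if (f$slope >= 0)
      return(utils::modifyList(none, list(flag = "no terminal decline",
                                          n_points = f$n, window = range(te[inw]))))
    return(list(lambda_z = -f$slope, r2_adj = f$r2_adj, n_points = f$n,
                window = range(te[inw]), flag = "ok"))
  }
  m <- length(te)
  if (m < 3) return(none)
  best <- NULL
  for (s in seq_len(m - 2L)) {
    f <- .loglin_fit(te[s:m], log(ce[s:m]))
    if (is.na(f$r2_adj)) next
    if (is.null(best) || f$r2_adj > best$r2_adj + 1e-12) best <- c(f, start = s)
    # ties (equal within 1e-12) keep the earlier, longer window
  }
  if (is.null(best)) return(none)
  if (best$slope >= 0)
    return(utils::modifyList(none, list(flag = "no terminal decline",
                                        n_points = best$n,
                                        window = range(te[best$start:m]))))
  list(lambda_z = -best$slope, r2_adj = best$r2_adj, n_points = best$n,
       window = range(te[best$start:m]), flag = "ok")
}

#' Extrapolate AUC to infinity
#'
#' `AUC0-inf = AUC0-t + Clast / lambda_z`, with the percent extrapolated
#' `100 * (AUC0-inf - AUC0-t) / AUC0-inf`.
#'
#' @param auc_0t AUC to the last measurable concentration, h·ng/mL.
#' @param c_last Last measurable concentration, ng/mL (> 0).
#' @param lambda_z Terminal rate, 1/h (> 0); `NA` propagates.
#' @return List with `auc_0inf` and `pct_extrapolated`.
#' @export
extrapolate_auc_inf <- function(auc_0t, c_last, lambda_z) {
  if (is.na(lambda_z))
    return(list(auc_0inf = NA_real_, pct_extrapolated = NA_real_))
  stopifnot(lambda_z > 0, c_last > 0, auc_0t > 0)
  auc_0inf <- auc_0t + c_last / lambda_z
  list(auc_0inf = auc_0inf,
       pct_extrapolated = 100 * (auc_0inf - auc_0t) / auc_0inf)
}

#' Half-life and apparent clearance
#'
#' `T1/2 = ln(2)/lambda_z`; `CL/F = dose/AUC0-inf`, with dose in mg and
#' AUC in h·ng/mL yielding L/h (dose converted to ug over ug·h/L).
#'
#' @param dose_mg Dose, mg (> 0).
#' @param auc_0inf AUC extrapolated to infinity, h·ng/mL (> 0, or `NA`).
#' @param lambda_z Terminal rate, 1/h (> 0, or `NA`).
#' @return List with `t_half` (h) and `cl_f` (L/h).
#' @export
#' @examples
#' derive_secondary(2, 11.9, 0.05)$cl_f # 168.07 L/h
derive_secondary <- function(dose_mg, auc_0inf, lambda_z) {
  if (dose_mg <= 0) stop("dose_mg must be > 0")
  if (!is.na(auc_0inf) && auc_0inf <= 0) stop("auc_0inf must be > 0")
  if (!is.na(lambda_z) && lambda_z <= 0) stop("lambda_z must be > 0")
  list(t_half = if (is.na(lambda_z)) NA_real_ else log(2) / lambda_z,
       cl_f = if (is.na(auc_0inf)) NA_real_ else mg_to_ug(dose_mg) / auc_0inf)
}

#' Full NCA for one subject
#'
#' @param profile A [concentration_profile()].
#' @param method AUC method, see [auc_linuplogdown()].
#' @param manual_window Optional terminal window, see [fit_lambda_z()].
#' @return One-row data.frame with columns `subject_id`, `dose_mg`,
#'   `cmax`, `tmax`, `auc_0t`, `auc_0inf`, `lambda_z`, `t_half`, `cl_f`,
#'   `lambda_z_n_points`, `lambda_z_r2_adj`, `pct_extrapolated`.
#'   Parameters that depend on an undefined `lambda_z` are `NA`.
#' @export
nca_profile <- function(profile, method = c("linuplogdown", "linear"),
                        manual_window = NULL) {
  method <- match.arg(method)
  p <- .prepared(profile)
  mx <- compute_cmax_tmax(p)
  auc_0t <- auc_linuplogdown(p, method = method)
  lz <- fit_lambda_z(p, manual_window = manual_window)
  c_last <- p$analysis_conc[length(p$analysis_conc)]
  ext <- if (!is.na(lz$lambda_z) && c_last > 0)
    extrapolate_auc_inf(auc_0t, c_last, lz$lambda_z)
  else list(auc_0inf = NA_real_, pct_extrapolated = NA_real_)
  sec <- derive_secondary(p$dose_mg, ext$auc_0inf, lz$lambda_z)
  data.frame(subject_id = p$subject_id, dose_mg = p$dose_mg,
             cmax = mx$cmax, tmax = mx$tmax, auc_0t = auc_0t,
             auc_0inf = ext$auc_0inf, lambda_z = lz$lambda_z,
             t_half = sec$t_half, cl_f = sec$cl_f,
             lambda_z_n_points = lz$n_points, lambda_z_r2_adj = lz$r2_adj,
             pct_extrapolated = ext$pct_extrapolated,
             stringsAsFactors = FALSE)
}

#' NCA for a whole study
#'
#' @param groups List of [dose_group()] objects (as from
#'   [read_profiles()] or [generate_cohort()]).
#' @inheritParams nca_profile
#' @return data.frame of per-subject [nca_profile()] rows.
#' @export
nca_study <- function(groups, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  do.call(rbind, unlist(lapply(groups, function(g)
    lapply(g$profiles, nca_profile, method = method)), recursive = FALSE))
}

#' Group-level summary of NCA results
#'
#' Geometric mean and geometric CV% for `cmax`, `auc_0t`, `auc_0inf`,
#' `t_half` and `cl_f`; median and range for `tmax` — the conventional
#' presentation of dose-escalation PK tables.
#'
#' @param results data.frame of [nca_profile()] rows (any mix of doses).
#' @return One row per dose with columns `dose_mg`, `n`,
#'   `<param>_geomean`, `<param>_geocv`, `tmax_median`, `tmax_min`,
#'   `tmax_max`.  Non-positive or missing parameter values are excluded
#'   from that parameter's summary with a warning.
#' @export
summarize_group <- function(results) {
  stopifnot(nrow(results) >= 1)
  params <- c("cmax", "auc_0t", "auc_0inf", "t_half", "cl_f")
  do.call(rbind, lapply(sort(unique(results$dose_mg)), function(d) {
    r <- results[results$dose_mg == d, ]
    row <- data.frame(dose_mg = d, n = nrow(r))
    for (p in params) {
      x <- r[[p]]
      bad <- is.na(x) | x <= 0
      if (any(bad))
        warning(sum(bad), " value(s) of ", p, " at ", d,
                " mg excluded from the geometric summary", call. = FALSE)
      x <- x[!bad]
      row[[paste0(p, "_geomean")]] <- if (length(x)) geo_mean(x) else NA_real_
      row[[paste0(p, "_geocv")]] <- if (length(x)) geo_cv(x) else NA_real_
    }
    row$tmax_median <- median(r$tmax)
    row$tmax_min <- min(r$tmax)
    row$tmax_max <- max(r$tmax)
    row
  }))
}
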