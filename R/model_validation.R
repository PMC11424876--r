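# Fold-error model validation: FE = predicted / observed, with the
# conventional 2-fold and 3-fold predictive-accuracy bands and the
# overall success rule FE in [0.3, 3] for every PK parameter.

#' Fold error of a prediction
#'
#' @param predicted,observed Positive values (vectorized).
#' @return `predicted / observed`.
#' @export
#' @examples
#' fold_error(0.41, 0.66) # 0.62 at 2 d.p.
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop("fold error requires strictly positive predicted and observed values")
  predicted / observed
}

#' Classify a fold error into accuracy bands
#'
#' Bands (closed edges): `within_2x` for FE in \[0.5, 2\], `within_3x`
#' for FE in \[1/3, 3\] but outside \[0.5, 2\], `beyond_3x` otherwise.
#' The success rule deems FE in \[0.3, 3\] a successful prediction.
#'
#' @param fe Positive fold error(s).
#' @return data.frame with columns `fe`, `band` (factor) and `success`
#'   (logical).
#' @export
classify_fe <- function(fe) {
  if (any(fe <= 0)) stop("fold errors must be positive")
  band <- ifelse(fe >= 0.5 & fe <= 2, "within_2x",
                 ifelse(fe >= 1 / 3 & fe <= 3, "within_3x", "beyond_3x"))
  data.frame(fe = fe,
             band = factor(band, levels = c("within_2x", "within_3x",
                                            "beyond_3x")),
             success = fe >= 0.3 & fe <= 3)
}

#' Fold-error report comparing predicted with observed PK
#'
#' Parameter-level entries compare predicted and observed Cmax and
#' AUC0-inf per dose; optional timepoint-level entries compare a
#' predicted dense curve with observed mean concentrations, matching
#' each observed time to the nearest grid time within 1% (supporting a
#' banded per-dose summary of concentration fold errors).
#'
#' @param prediction data.frame with `dose_mg`, `cmax`, `auc_0inf`
#'   (predicted; as from [dose_scan()]).
#' @param observed data.frame with `dose_mg`, `cmax`, `auc_0inf`
#'   (observed, e.g. group geometric means).
#' @param predicted_profiles Optional named list (by dose) of
#'   `pbpk_profile` objects or data.frames with `time_h`, `conc_ng_ml`.
#' @param observed_profiles Optional data.frame with `dose_mg`,
#'   `time_h`, `conc_ng_ml` of observed group mean concentrations.
#' @param time_match_tol Relative tolerance for timepoint matching.
#' @return An object of class `fold_error_report`: list with
#'   `parameters` (dose, parameter, predicted, observed, fe, band,
#'   success), optional `timepoints`, and the overall `success` flag
#'   (all parameter-level FE within \[0.3, 3\]).
#' @export
validate_predictions <- function(prediction, observed,
                                 predicted_profiles = NULL,
                                 observed_profiles = NULL,
                                 time_match_tol = 0.01) {
  missing_doses <- setdiff(observed$dose_mg, prediction$dose_mg)
  extra_doses <- setdiff(prediction$dose_mg, observed$dose_mg)
  if (length(missing_doses) || length(extra_doses))
    stop("validation error: unmatched dose levels: ",
         paste(sort(c(missing_doses, extra_doses)), collapse = ", "), " mg")
  obs <- observed[match(prediction$dose_mg, observed$dose_mg), ]
  param_rows <- do.call(rbind, lapply(c("cmax", "auc_0inf"), function(p) {
    fe <- fold_error(prediction[[p]], obs[[p]])
    cbind(data.frame(dose_mg = prediction$dose_mg, parameter = p,
                     predicted = prediction[[p]], observed = obs[[p]]),
          classify_fe(fe))
  }))
  tp_rows <- NULL
  if (!is.null(predicted_profiles) && !is.null(observed_profiles)) {
    tp_rows <- do.call(rbind, lapply(unique(observed_profiles$dose_mg),
                                     function(d) {
      op <- observed_profiles[observed_profiles$dose_mg == d &
                                observed_profiles$conc_ng_ml > 0, ]
      pp <- predicted_profiles[[as.character(d)]]
      if (is.null(pp)) stop("no predicted profile for dose ", d, " mg")
      idx <- vapply(op$time_h, function(t0) which.min(abs(pp$time_h - t0)),
                    integer(1))
      dt <- abs(pp$time_h[idx] - op$time_h)
      ok <- dt <= time_match_tol * pmax(op$time_h, 1e-9)
      if (!all(ok))
        stop("no grid time within ", 100 * time_match_tol,
             "% of observed time(s) ", paste(op$time_h[!ok], collapse = ", "),
             " h at ", d, " mg")
      pred_c <- pp$conc_ng_ml[idx]
      keep <- pred_c > 0
      fe <- fold_error(pred_c[keep], op$conc_ng_ml[keep])
      cbind(data.frame(dose_mg = d, time_h = op$time_h[keep],
                       predicted = pred_c[keep],
                       observed = op$conc_ng_ml[keep]),
            classify_fe(fe))
    }))
  }
  structure(list(parameters = param_rows, timepoints = tp_rows,
                 success = all(param_rows$success)),
            class = "fold_error_report")
}

#' @export
print.fold_error_report <- function(x, ...) {
  cat(sprintf("<fold_error_report> %d parameter entries, %s; overall %s\n",
              nrow(x$parameters),
              if (is.null(x$timepoints)) "no timepoint entries"
              else paste(nrow(x$timepoints), "timepoint entries"),
              if (x$success) "SUCCESS" else "FAILURE"))
  tab <- table(x$parameters$band)
  cat("  parameter bands:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Per-dose band counts of timepoint fold errors
#'
#' Summarizes the timepoint-level entries of a [validate_predictions()]
#' report as counts per accuracy band per dose.
#'
#' @param report A `fold_error_report` with timepoint entries.
#' @return data.frame with `dose_mg`, `within_2x`, `within_3x`,
#'   `beyond_3x`.
#' @export
band_summary <- function(report) {
  tp <- report$timepoints
  if (is.null(tp)) stop("report has no timepoint entries")
  tab <- table(tp$dose_mg, tp$band)
  out <- data.frame(dose_mg = as.numeric(rownames(tab)))
  for (b in colnames(tab)) out[[b]] <- as.integer(tab[, b])
  out
}
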