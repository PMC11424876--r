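# End-to-end orchestration: ingest or generate -> NCA -> dose
# proportionality -> (optional) PBPK calibrate + dose scan -> fold-error
# validation, with a report bundle written to disk.

#' Pipeline configuration
#'
#' @param input Either a path to a long-format concentration CSV or a
#'   [cohort_spec()] (exactly one source).
#' @param nca_method AUC method, see [auc_linuplogdown()].
#' @param theta_l,theta_h Proportionality limits for
#'   [acceptance_range()].
#' @param ci_level Confidence level for the power-model slope.
#' @param pbpk Optional list enabling the PBPK stage:
#'   `drug` ([drug_parameters()]), `physiology` (defaults to
#'   [default_physiology()]), `ka_init`, `cl_init`, `f_abs`, `tlag`,
#'   `reference_dose_mg`, and optional `targets = c(cmax, auc_0inf)`
#'   (defaulting to the observed geometric means of the reference dose
#'   group).  `NULL` skips calibration and validation.
#' @param out_dir Output directory for the report bundle.
#' @param seed Global seed recorded in the manifest and used for any
#'   synthetic generation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, nca_method = "linuplogdown",
                            theta_l = 0.8, theta_h = 1.25, ci_level = 0.90,
                            pbpk = NULL, out_dir = tempfile("fihpk_run_"),
                            seed = 20260101L) {
  is_path <- is.character(input) && length(input) == 1
  is_spec <- inherits(input, "cohort_spec")
  if (!xor(is_path, is_spec))
    stop("input must be exactly one of: a CSV path or a cohort_spec")
  if (!is.null(pbpk) && is.null(pbpk$reference_dose_mg))
    stop("pbpk configuration needs a reference_dose_mg")
  structure(list(input = input, nca_method = nca_method,
                 theta_l = theta_l, theta_h = theta_h, ci_level = ci_level,
                 pbpk = pbpk, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # hash the analysis settings, not the output location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data ingest (or synthetic-cohort generation), NCA
#' per subject plus group summaries, power-model dose-proportionality
#' assessment, and — when a PBPK section is configured — single-dose
#' calibration, dose scan, and fold-error validation against the
#' observed group geometric means.  Each stage failure aborts with a
#' stage-tagged error; outputs are written atomically to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `report_bundle` list: `nca`, `group_summary`,
#'   `doseprop` (+ `acceptance_range`), optional `prediction` and
#'   `fold_error`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  groups <- .stage("ingest", {
    if (inherits(config$input, "cohort_spec")) {
      spec <- config$input
      spec$seed <- config$seed
      generate_cohort(spec)
    } else read_profiles(config$input)
  })

  nca <- .stage("nca", nca_study(groups, method = config$nca_method))
  n_missing <- sum(is.na(nca$lambda_z))
  if (n_missing > 0)
    warning(n_missing, " subject(s) with undefined lambda_z; dependent ",
            "parameters reported missing", call. = FALSE)
  summary <- .stage("nca", suppressWarnings(summarize_group(nca)))

  doseprop <- .stage("doseprop", {
    rng <- acceptance_range(config$theta_l, config$theta_h,
                            max(nca$dose_mg) / min(nca$dose_mg))
    rows <- lapply(c("cmax", "auc_0t", "auc_0inf"), function(p) {
      ok <- !is.na(nca[[p]])
      fit <- fit_power_model(nca$dose_mg[ok], nca[[p]][ok], p,
                             ci_level = config$ci_level)
      v <- assess_proportionality(fit, rng)
      data.frame(parameter = p, beta = fit$beta,
                 ci_low = fit$ci[1], ci_high = fit$ci[2],
                 range_low = rng$low, range_high = rng$high,
                 verdict = v$verdict, rationale = v$rationale)
    })
    list(table = do.call(rbind, rows), range = rng)
  })

  prediction <- fe_report <- NULL
  if (!is.null(config$pbpk)) {
    pb <- config$pbpk
    prediction <- .stage("pbpk", {
      drug <- if (is.null(pb$drug)) drug_parameters() else pb$drug
      phys <- if (is.null(pb$physiology)) default_physiology() else pb$physiology
      model <- build_model(
        drug, phys,
        absorption_model(ka = if (is.null(pb$ka_init)) 1 else pb$ka_init,
                         f_abs = if (is.null(pb$f_abs)) 1 else pb$f_abs,
                         tlag = if (is.null(pb$tlag)) 0 else pb$tlag),
        elimination_model(if (is.null(pb$cl_init)) 100 else pb$cl_init))
      targets <- pb$targets
      if (is.null(targets)) {
        ref <- summary[summary$dose_mg == pb$reference_dose_mg, ]
        if (nrow(ref) != 1)
          stop("reference dose ", pb$reference_dose_mg, " mg not in the data")
        targets <- c(ref$cmax_geomean, ref$auc_0inf_geomean)
      }
      model <- calibrate(model, pb$reference_dose_mg, targets[1], targets[2])
      list(model = model, table = dose_scan(model, summary$dose_mg))
    })
    fe_report <- .stage("validate", {
      obs <- data.frame(dose_mg = summary$dose_mg,
                        cmax = summary$cmax_geomean,
                        auc_0inf = summary$auc_0inf_geomean)
      validate_predictions(prediction$table, obs)
    })
  }

  manifest <- list(package = "fihpk",
                   version = as.character(utils::packageVersion("fihpk")),
                   seed = config$seed, config_hash = .config_hash(config),
                   stages = c("ingest", "nca", "doseprop",
                              if (!is.null(config$pbpk)) c("pbpk", "validate")))

  .write_csv_atomic(nca, file.path(config$out_dir, "nca_subjects.csv"))
  .write_csv_atomic(summary, file.path(config$out_dir, "group_summary.csv"))
  .write_csv_atomic(doseprop$table, file.path(config$out_dir, "doseprop.csv"))
  if (!is.null(prediction)) {
    .write_csv_atomic(prediction$table, file.path(config$out_dir, "prediction.csv"))
    .write_csv_atomic(fe_report$parameters, file.path(config$out_dir, "fold_error.csv"))
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(config$out_dir, "manifest.json"))

  invisible(structure(list(nca = nca, group_summary = summary,
                           doseprop = doseprop$table,
                           acceptance_range = doseprop$range,
                           prediction = prediction$table,
                           fold_error = fe_report, manifest = manifest),
                      class = "report_bundle"))
}
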