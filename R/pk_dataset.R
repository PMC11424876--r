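# Domain types and I/O for concentration-time data.
#
# A concentration_profile holds one subject's sampled plasma curve; BLQ
# (below the lower limit of quantification) points are carried as
# explicit markers, never silently as zeros, so that the analysis-time
# policy for them is a documented, reversible decision.

#' Construct a single-subject concentration-time profile
#'
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param dose_mg Administered dose in mg; must be positive.
#' @param time_h Sampling times in hours post-dose.  Stored sorted
#'   ascending; duplicates are an error.
#' @param conc_ng_ml Plasma concentrations in ng/mL, one per time.  Use
#'   `NA` (with `blq = TRUE`) for below-limit-of-quantification points.
#' @param blq Logical vector marking BLQ points.  Defaults to
#'   `is.na(conc_ng_ml)`.
#' @return An object of class `concentration_profile`.
#' @export
#' @examples
#' concentration_profile("S1", 2, c(0, 1, 2), c(NA, 5, 3), blq = c(TRUE, FALSE, FALSE))
concentration_profile <- function(subject_id, dose_mg, time_h, conc_ng_ml,
                                  blq = is.na(conc_ng_ml)) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, length(dose_mg) == 1L)
  if (!is.finite(dose_mg) || dose_mg <= 0) stop("dose_mg must be > 0")
  n <- length(time_h)
  if (length(conc_ng_ml) != n || length(blq) != n)
    stop("time_h, conc_ng_ml and blq must have equal length")
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("sampling times must be finite and >= 0")
  ord <- order(time_h)
  time_h <- time_h[ord]; conc_ng_ml <- conc_ng_ml[ord]; blq <- as.logical(blq[ord])
  if (anyDuplicated(time_h))
    stop("duplicate sampling time for subject '", subject_id, "'")
  if (any(!blq & (!is.finite(conc_ng_ml) | conc_ng_ml < 0)))
    stop("quantified concentrations must be finite and >= 0")
  conc_ng_ml[blq] <- NA_real_
  structure(
    list(subject_id = subject_id, dose_mg = as.numeric(dose_mg),
         time_h = as.numeric(time_h), conc_ng_ml = as.numeric(conc_ng_ml),
         blq = blq),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> subject %s, %g mg, %d points (%d BLQ)\n",
              x$subject_id, x$dose_mg, length(x$time_h), sum(x$blq)))
  invisible(x)
}

#' Group profiles that share a dose level
#'
#' @param dose_mg Common dose of the group, mg.
#' @param profiles List of [concentration_profile()] objects, all with
#'   `dose_mg` equal to the group dose.
#' @return An object of class `dose_group`.
#' @export
dose_group <- function(dose_mg, profiles) {
  if (length(profiles) < 1) stop("a dose group needs at least one profile")
  ok <- vapply(profiles, function(p)
    inherits(p, "concentration_profile") && isTRUE(all.equal(p$dose_mg, dose_mg)),
    logical(1))
  if (!all(ok)) stop("all member profiles must share the group dose (", dose_mg, " mg)")
  structure(list(dose_mg = as.numeric(dose_mg), profiles = profiles),
            class = "dose_group")
}

#' Single-ascending-dose study design
#'
#' Defaults reproduce the NH130 phase I escalation design: seven dose
#' levels 2/6/12/24/40/60/90 mg, two active subjects at 2 mg and eight at
#' every other level, the 16-point sampling schedule from 0 to 96 h, and
#' an assay lower limit of quantification of 0.05 ng/mL.
#'
#' @param dose_levels_mg Strictly increasing dose levels, mg.
#' @param group_sizes Active subjects per dose level.
#' @param schedule_h Nominal sampling times, hours post-dose.
#' @param lloq_ng_ml Lower limit of quantification, ng/mL (> 0).
#' @return An object of class `study_design`.
#' @export
study_design <- function(dose_levels_mg = c(2, 6, 12, 24, 40, 60, 90),
                         group_sizes = c(2, rep(8, length(dose_levels_mg) - 1L)),
                         schedule_h = c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8,
                                        12, 24, 36, 48, 72, 96),
                         lloq_ng_ml = 0.05) {
  if (is.unsorted(dose_levels_mg, strictly = TRUE))
    stop("dose_levels_mg must be strictly increasing")
  if (length(group_sizes) != length(dose_levels_mg))
    stop("group_sizes must match dose_levels_mg in length")
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  if (lloq_ng_ml <= 0) stop("lloq_ng_ml must be > 0")
  structure(list(dose_levels_mg = dose_levels_mg,
                 group_sizes = as.integer(group_sizes),
                 schedule_h = schedule_h, lloq_ng_ml = lloq_ng_ml),
            class = "study_design")
}

.default_dialect <- list(subject = "subject", dose = "dose_mg",
                         time = "time_h", conc = "conc_ng_ml")

#' Read long-format concentration-time data
#'
#' Expects a long CSV with one row per (subject, time) observation.  The
#' default header is `subject,dose_mg,time_h,conc_ng_ml`; other column
#' names can be mapped through `dialect`.  BLQ points are encoded either
#' by the designated token (default `"BLQ"`) or, when `lloq_ng_ml` is
#' supplied, by any value strictly below it.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping the roles `subject`, `dose`, `time`,
#'   `conc` to column names in the file.
#' @param blq_token Character token marking BLQ concentrations.
#' @param lloq_ng_ml Optional LLOQ; numeric values below it become BLQ.
#' @return A list of [dose_group()] objects, ordered by increasing dose.
#' @export
read_profiles <- function(path, dialect = .default_dialect,
                          blq_token = "BLQ", lloq_ng_ml = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- utils::modifyList(.default_dialect, as.list(dialect))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  need <- unlist(dialect[c("subject", "dose", "time", "conc")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste0("'", missing_cols, "'", collapse = ", "))

  parse_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("parse error: non-numeric ", what, " on data line(s) ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    v
  }
  subject <- raw[[dialect$subject]]
  dose <- parse_num(raw[[dialect$dose]], "dose")
  time <- parse_num(raw[[dialect$time]], "time")
  conc_raw <- raw[[dialect$conc]]
  is_blq <- conc_raw == blq_token
  conc <- rep(NA_real_, length(conc_raw))
  if (any(!is_blq)) {
    v <- suppressWarnings(as.numeric(conc_raw[!is_blq]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("parse error: non-numeric concentration on data line(s) ",
           paste(which(!is_blq)[bad] + 1L, collapse = ", "))
    conc[!is_blq] <- v
  }
  if (!is.null(lloq_ng_ml)) {
    below <- !is_blq & conc < lloq_ng_ml
    is_blq[below] <- TRUE
    conc[below] <- NA_real_
  }
  dup <- duplicated(data.frame(subject, time))
  if (any(dup))
    stop("validation error: duplicate (subject, time) on data line(s) ",
         paste(which(dup) + 1L, collapse = ", "))

  groups <- lapply(sort(unique(dose)), function(d) {
    idx <- dose == d
    profs <- lapply(unique(subject[idx]), function(s) {
      i <- idx & subject == s
      concentration_profile(s, d, time[i], conc[i], blq = is_blq[i])
    })
    dose_group(d, profs)
  })
  groups
}

#' Write dose groups as long-format CSV
#'
#' Inverse of [read_profiles()]: `read_profiles(write_profiles(x))`
#' reproduces `x` field-for-field, including BLQ markers.
#'
#' @param groups Non-empty list of [dose_group()] objects.
#' @param path Output CSV path.
#' @param blq_token Token used for BLQ concentrations.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(groups, path, blq_token = "BLQ") {
  if (length(groups) == 0) stop("nothing to write: empty group list")
  rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(g$profiles, function(p) {
      data.frame(subject = p$subject_id,
                 dose_mg = sprintf("%.17g", p$dose_mg),
                 time_h = sprintf("%.17g", p$time_h),
                 conc_ng_ml = ifelse(p$blq, blq_token,
                                     sprintf("%.17g", p$conc_ng_ml)),
                 stringsAsFactors = FALSE)
    }))
  }))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prepare a profile's BLQ points for analysis
#'
#' Standard NCA convention for single-dose data: BLQ points *before* the
#' first quantifiable concentration are set to zero (the drug has not
#' yet appeared), while BLQ points *after* it are excluded from AUC and
#' terminal-slope computations but retained on the object for record.
#' The operation is idempotent.
#'
#' @param profile A [concentration_profile()].
#' @param leading_blq One of `"zero"` (default) or `"exclude"`.
#' @return The profile with `analysis_time_h` / `analysis_conc` fields
#'   (the prepared vectors), `excluded_time_h`, and a `blq_policy`
#'   attribute.  Errors with "no quantifiable data" when every point is
#'   BLQ.
#' @export
blq_policy <- function(profile, leading_blq = c("zero", "exclude")) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (!is.null(attr(profile, "blq_policy"))) return(profile)
  leading_blq <- match.arg(leading_blq)
  quantified <- !profile$blq
  if (!any(quantified))
    stop("no quantifiable data for subject '", profile$subject_id, "'")
  first_q <- which(quantified)[1L]
  idx <- seq_along(profile$time_h)
  lead <- profile$blq & idx < first_q
  late <- profile$blq & idx > first_q

  keep <- quantified | (lead & leading_blq == "zero")
  conc <- profile$conc_ng_ml
  conc[lead] <- 0
  profile$analysis_time_h <- profile$time_h[keep]
  profile$analysis_conc <- conc[keep]
  profile$excluded_time_h <- profile$time_h[late]
  attr(profile, "blq_policy") <-
    sprintf("leading BLQ -> %s; post-first-quantifiable BLQ -> excluded",
            leading_blq)
  profile
}
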