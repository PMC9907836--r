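#' Read a cohort from CSV files
#'
#' Ingests the long CVP measurement table and the patient-level covariate
#' table written by [export_cohort()] (or prepared by the user in the same
#' layout).
#'
#' @param events_csv Path to `cvp_events.csv` with header
#'   `patient_id,time_hr,cvp_mmhg`.
#' @param patients_csv Path to `patients.csv`, one row per patient.
#'
#' @return A list with elements `events` and `patients` (data.frames,
#'   ordered by patient id and time).
#' @export
ingest_cohort <- function(events_csv, patients_csv) {
  for (p in c(events_csv, patients_csv))
    if (!file.exists(p)) stop("input file not found: ", p)
  events <- as.data.frame(data.table::fread(events_csv))
  patients <- as.data.frame(data.table::fread(patients_csv))
  events <- check_events(events)
  if (!"patient_id" %in% names(patients))
    stop("patients table lacks a patient_id column: ", patients_csv)
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id rows in ", patients_csv)
  events <- events[order(events$patient_id, events$time_hr), , drop = FALSE]
  rownames(events) <- NULL
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(patients) <- NULL
  list(events = events, patients = patients)
}

#' Drop physiologically implausible CVP values
#'
#' Removes measurements outside the configured plausibility band (default
#' 0–50 mmHg) before any selection or area computation, so charting
#' artifacts cannot dominate trapezoid areas.
#'
#' @param events Long measurement table (`patient_id,time_hr,cvp_mmhg`) or
#'   a single [cvp_series()].
#' @param cfg A [cohort_config()].
#' @return Input of the same shape, artifact rows removed; the number
#'   dropped is attached as attribute `n_dropped` and reported via
#'   `message()`.
#' @export
clean_values <- function(events, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (inherits(events, "cvp_series")) {
    keep <- events$values >= cfg$value_floor_mmhg &
      events$values <= cfg$value_ceiling_mmhg
    if (!any(keep))
      stop("patient ", events$patient_id,
           ": no measurements inside the plausibility band")
    out <- cvp_series(events$patient_id, events$times[keep],
                      events$values[keep])
    attr(out, "n_dropped") <- sum(!keep)
    return(out)
  }
  events <- check_events(events)
  keep <- events$cvp_mmhg >= cfg$value_floor_mmhg &
    events$cvp_mmhg <= cfg$value_ceiling_mmhg
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("clean_values: dropped ", n_dropped, " measurement(s) outside [",
            cfg$value_floor_mmhg, ", ", cfg$value_ceiling_mmhg, "] mmHg")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Apply the cohort inclusion and exclusion windows
#'
#' A patient is kept iff: a CVP series exists, the first measurement falls
#' at or before `start_limit_hr` (monitoring started within the first 24 h
#' by default), the last measurement of the full untruncated stream reaches
#' `window_hr` (monitoring did not end before 72 h), and age is at least
#' `min_age_years`. Exclusions are reported under a fixed precedence —
#' no-CVP, then age, then late start, then early end — so flowchart counts
#' are deterministic.
#'
#' @param events Long measurement table (already passed through
#'   [clean_values()] if artifact filtering is wanted).
#' @param patients Patient-level table with at least `patient_id` and
#'   `age`.
#' @param cfg A [cohort_config()].
#'
#' @return A list: `events` and `patients` restricted to included patients,
#'   and `report`, a `selection_report` with counts (`n_input`,
#'   `n_excluded_no_cvp`, `n_excluded_age`, `n_excluded_late_start`,
#'   `n_excluded_early_end`, `n_included`) and a per-patient `reasons`
#'   data.frame.
#' @export
select_patients <- function(events, patients, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  events <- check_events(events)
  if (!all(c("patient_id", "age") %in% names(patients)))
    stop("patients table needs columns patient_id and age")
  patients$patient_id <- as.character(patients$patient_id)

  first_t <- tapply(events$time_hr, events$patient_id, min)
  last_t <- tapply(events$time_hr, events$patient_id, max)
  ids <- patients$patient_id
  has_cvp <- ids %in% names(first_t)

  reason <- rep(NA_character_, length(ids))
  reason[!has_cvp] <- "no_cvp"
  age_ok <- patients$age >= cfg$min_age_years
  reason[is.na(reason) & !age_ok] <- "age"
  start_ok <- rep(FALSE, length(ids))
  start_ok[has_cvp] <- first_t[ids[has_cvp]] <= cfg$start_limit_hr
  reason[is.na(reason) & !start_ok] <- "late_start"
  end_ok <- rep(FALSE, length(ids))
  end_ok[has_cvp] <- last_t[ids[has_cvp]] >= cfg$window_hr
  reason[is.na(reason) & !end_ok] <- "early_end"

  included <- is.na(reason)
  report <- structure(
    list(
      n_input = length(ids),
      n_excluded_no_cvp = sum(reason == "no_cvp", na.rm = TRUE),
      n_excluded_age = sum(reason == "age", na.rm = TRUE),
      n_excluded_late_start = sum(reason == "late_start", na.rm = TRUE),
      n_excluded_early_end = sum(reason == "early_end", na.rm = TRUE),
      n_included = sum(included),
      reasons = data.frame(patient_id = ids,
                           included = included,
                           reason = ifelse(included, "included", reason))
    ),
    class = "selection_report"
  )
  keep_ids <- ids[included]
  list(
    events = events[events$patient_id %in% keep_ids, , drop = FALSE],
    patients = patients[included, , drop = FALSE],
    report = report
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  input:            ", x$n_input, "\n")
  cat("  excluded no CVP:  ", x$n_excluded_no_cvp, "\n")
  cat("  excluded age:     ", x$n_excluded_age, "\n")
  cat("  excluded start>limit:", x$n_excluded_late_start, "\n")
  cat("  excluded end<window: ", x$n_excluded_early_end, "\n")
  cat("  included:         ", x$n_included, "\n")
  invisible(x)
}

#' Truncate a CVP stream to the analysis window
#'
#' Retains exactly the measurements with `time_hr <= window_hr` (the
#' boundary is inclusive: a measurement at exactly 72 h is analyzed). No
#' boundary interpolation is performed.
#'
#' @param s A [cvp_series()], or a long measurement table.
#' @param cfg A [cohort_config()].
#' @return Object of the same shape, truncated.
#' @export
truncate_series <- function(s, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (inherits(s, "cvp_series")) {
    keep <- s$times <= cfg$window_hr
    if (!any(keep))
      stop("patient ", s$patient_id, ": no measurements at or before ",
           cfg$window_hr, " h; nothing to analyze")
    return(cvp_series(s$patient_id, s$times[keep], s$values[keep]))
  }
  s <- check_events(s)
  out <- s[s$time_hr <= cfg$window_hr, , drop = FALSE]
  rownames(out) <- NULL
  out
}
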