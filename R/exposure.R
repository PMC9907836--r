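#' Segment a CVP series and classify elevated intervals
#'
#' Splits a series of N measurements into the N-1 inter-measurement
#' intervals. Each segment carries its endpoint-mean CVP and its full
#' trapezoid area `mean * length`; a segment is elevated (ECVP) when its
#' endpoint mean strictly exceeds the threshold. Segments are classified
#' whole: an interval whose endpoints straddle the threshold is not split at
#' an interpolated crossing point.
#'
#' @param s A [cvp_series()] with at least two measurements.
#' @param threshold ECVP threshold in mmHg (default 10).
#'
#' @return A data.frame with one row per segment: `t_start`, `t_end`,
#'   `v_start`, `v_end`, `mean_cvp`, `length_hr`, `area`, `is_ecvp`.
#' @examples
#' build_segments(cvp_series("P1", c(0, 1, 3), c(12, 14, 8)))
#' @export
build_segments <- function(s, threshold = 10) {
  stopifnot(inherits(s, "cvp_series"))
  n <- length(s$times)
  if (n < 2L)
    stop("patient ", s$patient_id,
         ": need at least 2 measurements to form segments")
  i <- seq_len(n - 1L)
  mean_cvp <- (s$values[i] + s$values[i + 1L]) / 2
  len <- s$times[i + 1L] - s$times[i]
  data.frame(
    t_start = s$times[i], t_end = s$times[i + 1L],
    v_start = s$values[i], v_end = s$values[i + 1L],
    mean_cvp = mean_cvp, length_hr = len, area = mean_cvp * len,
    is_ecvp = mean_cvp > threshold
  )
}

#' Trapezoidal CVP exposure metrics for one patient
#'
#' Computes the time-weighted exposure quantities for a (truncated) CVP
#' series: total and elevated-CVP load (trapezoidal areas under the
#' piecewise-linear CVP curve, mmHg·hr), monitoring and elevated durations
#' (hr), and the normalized loads (load / own duration — time-weighted mean
#' pressures, mmHg). `avg_ecvp_load` dilutes the elevated exposure over the
#' whole monitored period (ECVP load / CVP duration).
#'
#' When a patient has no elevated segment, `norm_ecvp_load` is recorded as
#' 0 with `norm_ecvp_defined = FALSE`; downstream exposure grouping treats
#' such patients as minimally exposed.
#'
#' @inheritParams build_segments
#' @return A list of class `exposure_metrics` with fields `patient_id`,
#'   `cvp_duration_hr`, `ecvp_duration_hr`, `cvp_load`, `ecvp_load`,
#'   `norm_cvp_load`, `norm_ecvp_load`, `avg_ecvp_load`,
#'   `pct_ecvp_duration`, `norm_ecvp_defined`.
#' @examples
#' compute_metrics(cvp_series("P1", c(0, 1, 3), c(12, 14, 8)))
#' @export
compute_metrics <- function(s, threshold = 10) {
  seg <- build_segments(s, threshold)
  cvp_duration <- s$times[length(s$times)] - s$times[1]
  ecvp_load <- sum(seg$area[seg$is_ecvp])
  ecvp_duration <- sum(seg$length_hr[seg$is_ecvp])
  # summed by class so the elevated/non-elevated decomposition is exact
  cvp_load <- ecvp_load + sum(seg$area[!seg$is_ecvp])
  defined <- ecvp_duration > 0
  structure(
    list(
      patient_id = s$patient_id,
      cvp_duration_hr = cvp_duration,
      ecvp_duration_hr = ecvp_duration,
      cvp_load = cvp_load,
      ecvp_load = ecvp_load,
      norm_cvp_load = cvp_load / cvp_duration,
      norm_ecvp_load = if (defined) ecvp_load / ecvp_duration else 0,
      avg_ecvp_load = ecvp_load / cvp_duration,
      pct_ecvp_duration = 100 * ecvp_duration / cvp_duration,
      norm_ecvp_defined = defined
    ),
    class = "exposure_metrics"
  )
}

#' Exposure metrics for a whole cohort
#'
#' Vectorized cohort-level version of [compute_metrics()], operating on a
#' long measurement table. Patients with fewer than two in-window
#' measurements cannot form a segment and are reported as failures rather
#' than aborting the run.
#'
#' @param events Data frame with columns `patient_id`, `time_hr`,
#'   `cvp_mmhg`; rows need not be ordered.
#' @param cfg A [cohort_config()]; supplies the ECVP threshold.
#'
#' @return A data.frame with one row per successful patient, ordered by
#'   `patient_id`, with the [compute_metrics()] fields as columns, plus an
#'   attribute `failures`: a character vector of patient ids with
#'   degenerate series.
#' @export
compute_cohort_metrics <- function(events, cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  events <- check_events(events)
  thr <- cfg$ecvp_threshold_mmhg
  dt <- data.table::as.data.table(events)
  data.table::setorder(dt, patient_id, time_hr)
  res <- dt[, {
    if (.N < 2L) {
      list(cvp_duration_hr = NA_real_, ecvp_duration_hr = NA_real_,
           cvp_load = NA_real_, ecvp_load = NA_real_,
           norm_cvp_load = NA_real_, norm_ecvp_load = NA_real_,
           avg_ecvp_load = NA_real_, pct_ecvp_duration = NA_real_,
           norm_ecvp_defined = NA)
    } else {
      len <- diff(time_hr)
      m <- (cvp_mmhg[-1L] + cvp_mmhg[-.N]) / 2
      a <- m * len
      e <- m > thr
      cvp_dur <- time_hr[.N] - time_hr[1L]
      ecvp_dur <- sum(len[e])
      ecvp_load <- sum(a[e])
      cvp_load <- ecvp_load + sum(a[!e])
      def <- ecvp_dur > 0
      list(cvp_duration_hr = cvp_dur, ecvp_duration_hr = ecvp_dur,
           cvp_load = cvp_load, ecvp_load = ecvp_load,
           norm_cvp_load = cvp_load / cvp_dur,
           norm_ecvp_load = if (def) ecvp_load / ecvp_dur else 0,
           avg_ecvp_load = ecvp_load / cvp_dur,
           pct_ecvp_duration = 100 * ecvp_dur / cvp_dur,
           norm_ecvp_defined = def)
    }
  }, by = patient_id]
  data.table::setorder(res, patient_id)
  failures <- res$patient_id[is.na(res$cvp_load)]
  if (length(failures))
    warning(length(failures), " patient(s) with < 2 in-window measurements",
            " skipped: ", paste(utils::head(failures, 5), collapse = ", "),
            if (length(failures) > 5) ", ..." else "")
  out <- as.data.frame(res[!is.na(res$cvp_load)])
  attr(out, "failures") <- failures
  out
}

# shared column/shape validation for long event tables
check_events <- function(events) {
  need <- c("patient_id", "time_hr", "cvp_mmhg")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop("events must be a data frame with columns ",
         paste(need, collapse = ", "))
  events$patient_id <- as.character(events$patient_id)
  if (!all(is.finite(events$time_hr)) || !all(is.finite(events$cvp_mmhg)))
    stop("events contain non-finite times or values")
  events
}
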