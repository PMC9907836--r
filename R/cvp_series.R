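#' Construct a single-patient CVP series
#'
#' A `cvp_series` holds one patient's irregular central venous pressure
#' measurement stream on the hours-from-ICU-admission axis.
#'
#' @param patient_id Scalar identifier (coerced to character).
#' @param times Numeric vector of measurement times in hours since ICU
#'   admission; must be finite, non-negative and strictly increasing.
#' @param values Numeric vector of CVP values in mmHg, same length as
#'   `times`; must be finite.
#'
#' @return An object of class `cvp_series`: a list with elements
#'   `patient_id`, `times` and `values`.
#' @examples
#' s <- cvp_series("P1", c(0, 1, 3), c(12, 14, 8))
#' compute_metrics(s)
#' @export
cvp_series <- function(patient_id, times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(patient_id) != 1L) stop("patient_id must be a scalar")
  if (length(times) != length(values))
    stop("times and values must have the same length (patient ",
         patient_id, ")")
  if (length(times) < 1L) stop("a cvp_series needs at least one measurement")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite (patient ", patient_id, ")")
  if (any(times < 0)) stop("times must be >= 0 (patient ", patient_id, ")")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing (patient ", patient_id, ")")
  structure(
    list(patient_id = as.character(patient_id), times = times,
         values = values),
    class = "cvp_series"
  )
}

#' @export
print.cvp_series <- function(x, ...) {
  cat(sprintf("<cvp_series> patient %s: %d measurements over [%.2f, %.2f] h\n",
              x$patient_id, length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.cvp_series <- function(x) length(x$times)

#' Cohort selection and exposure-window configuration
#'
#' Thresholds and windows governing cohort selection, series truncation and
#' the elevated-CVP definition.
#'
#' @param start_limit_hr Latest admissible first CVP measurement, hours from
#'   ICU admission (default 24).
#' @param window_hr Analysis window: only measurements at `time <=
#'   window_hr` are analyzed, and the full stream must reach this far for a
#'   patient to be included (default 72).
#' @param ecvp_threshold_mmhg CVP level above which an inter-measurement
#'   interval counts as elevated CVP; classification uses the strict
#'   inequality segment mean `> threshold` (default 10).
#' @param min_age_years Minimum age for inclusion (default 18).
#' @param value_floor_mmhg,value_ceiling_mmhg Plausibility bounds; values
#'   outside `[floor, ceiling]` are dropped as charting artifacts (defaults
#'   0 and 50).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(start_limit_hr = 24, window_hr = 72,
                          ecvp_threshold_mmhg = 10, min_age_years = 18,
                          value_floor_mmhg = 0, value_ceiling_mmhg = 50) {
  cfg <- list(start_limit_hr = start_limit_hr, window_hr = window_hr,
              ecvp_threshold_mmhg = ecvp_threshold_mmhg,
              min_age_years = min_age_years,
              value_floor_mmhg = value_floor_mmhg,
              value_ceiling_mmhg = value_ceiling_mmhg)
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cohort_config: field '", f, "' must be a finite numeric scalar")
  }
  if (cfg$start_limit_hr <= 0 || cfg$start_limit_hr >= cfg$window_hr)
    stop("cohort_config: need 0 < start_limit_hr < window_hr")
  if (cfg$ecvp_threshold_mmhg <= 0)
    stop("cohort_config: ecvp_threshold_mmhg must be > 0")
  if (cfg$value_floor_mmhg >= cfg$value_ceiling_mmhg)
    stop("cohort_config: value_floor_mmhg must be below value_ceiling_mmhg")
  structure(cfg, class = "cohort_config")
}
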