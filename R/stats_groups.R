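#' Split a cohort at the median of an exposure metric
#'
#' Dichotomizes the cohort at the sample median of the given column:
#' values strictly above the median form the high-exposure group, values
#' at or below it (including patients whose normalized ECVP load is
#' undefined and recorded as 0) the low-exposure group. The tie rule is
#' explicit because with charted (discrete) pressures many patients can
#' sit exactly at the median.
#'
#' @param metrics Data.frame of per-patient exposure metrics.
#' @param key Column to split on (default `"norm_ecvp_load"`).
#' @return A list of class `median_split`: `threshold`, `group` (factor
#'   `"low"`/`"high"` aligned with `metrics` rows), `n_high`, `n_low`.
#' @export
median_split <- function(metrics, key = "norm_ecvp_load") {
  x <- metrics[[key]]
  if (is.null(x)) stop("column not found: ", key)
  if (length(x) < 2L) stop("median split needs at least 2 patients")
  if (length(unique(x)) == 1L)
    stop("all '", key, "' values identical; median split impossible")
  thr <- stats::median(x)
  grp <- factor(ifelse(x > thr, "high", "low"), levels = c("low", "high"))
  structure(list(threshold = thr, group = grp,
                 n_high = sum(grp == "high"), n_low = sum(grp == "low")),
            class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf("<median_split> threshold %.3g: %d high / %d low\n",
              x$threshold, x$n_high, x$n_low))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimate per exposure group over the 28-day
#' follow-up, with the two-group log-rank test.
#'
#' @param records Data.frame with `survival_days` (in (0, 28]) and
#'   `death_28d` (0/1; survivors censored at 28 days).
#' @param group Factor/vector of group labels aligned with `records`
#'   rows.
#' @return A list of class `km_result`: `curves` (data.frame `group`,
#'   `time`, `surv`, `n_risk`, `n_event`), `chisq`, `p_value`, `flag`
#'   (`"ok"` or `"no_events"`).
#' @export
km_logrank <- function(records, group) {
  group <- factor(group)
  if (any(table(group) == 0L) || length(levels(group)) < 2L)
    stop("km_logrank needs at least two non-empty groups")
  if (!all(c("survival_days", "death_28d") %in% names(records)))
    stop("records need columns survival_days and death_28d")
  if (any(records$survival_days <= 0) || any(records$survival_days > 28))
    stop("survival_days must lie in (0, 28]")
  su <- survival::Surv(records$survival_days, records$death_28d)
  fit <- survival::survfit(su ~ group)
  sm <- summary(fit)
  curves <- data.frame(
    group = sub("^group=", "", as.character(sm$strata)),
    time = sm$time, surv = sm$surv, n_risk = sm$n.risk, n_event = sm$n.event
  )
  if (sum(records$death_28d) == 0L)
    return(structure(list(curves = curves, chisq = NA_real_, p_value = 1,
                          flag = "no_events"), class = "km_result"))
  sd <- survival::survdiff(su ~ group)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd$chisq), p_value = p,
                 flag = "ok"), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> log-rank chisq = %.3f, p = %.4g (%s)\n",
              x$chisq, x$p_value, x$flag))
  invisible(x)
}

#' Crude exposure-mortality relationship by lowess smoothing
#'
#' Bins patients by integer-rounded normalized ECVP load, reports the raw
#' mortality rate per bin, and fits a lowess curve through the per-patient
#' (load, death) points. Empty integer bins inside the observed range are
#' reported, mirroring dose-response bar plots where some integer loads
#' have no patients.
#'
#' @param data Data.frame with the exposure column and `death_28d`.
#' @param key Exposure column (default `"norm_ecvp_load"`).
#' @param span Lowess smoother span in (0, 1] (default 0.8).
#' @param min_bins Minimum number of non-empty integer bins (default 5).
#' @return A list of class `lowess_mortality`: `bins` (data.frame `bin`,
#'   `n`, `mortality`), `smooth` (data.frame `x`, `y` sorted by `x`),
#'   `empty_bins` (integer vector), `overall_rate`.
#' @export
lowess_mortality <- function(data, key = "norm_ecvp_load", span = 0.8,
                             min_bins = 5) {
  x <- data[[key]]
  y <- data$death_28d
  if (is.null(x) || is.null(y)) stop("need columns ", key, " and death_28d")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  bin <- round(x)
  tab <- table(bin)
  if (length(tab) < min_bins)
    stop("only ", length(tab), " non-empty exposure bins (need >= ",
         min_bins, "); consider wider bins or a larger cohort")
  bins <- data.frame(
    bin = as.integer(names(tab)),
    n = as.integer(tab),
    mortality = as.numeric(tapply(y, bin, mean))
  )
  empty <- setdiff(seq(min(bins$bin), max(bins$bin)), bins$bin)
  # iter = 0: robustness reweighting would treat the binary 1s as outliers
  # and collapse the curve toward 0
  lw <- stats::lowess(x, y, f = span, iter = 0)
  structure(list(bins = bins,
                 smooth = data.frame(x = lw$x, y = lw$y),
                 empty_bins = as.integer(empty),
                 overall_rate = mean(y)),
            class = "lowess_mortality")
}

#' Within-quartile comparison of ECVP duration by survival
#'
#' Divides the cohort into quartiles of ECVP load (boundary values
#' assigned to the lower quartile) — so that patients within a subgroup
#' have comparable elevated-CVP exposure — and, within each quartile,
#' compares the ECVP duration and the percentage of ECVP duration in total
#' CVP duration between survivors and non-survivors with the Wilcoxon
#' rank-sum test. A quartile containing a single outcome class is skipped
#' with a flag.
#'
#' @param data Data.frame with `ecvp_load`, `ecvp_duration_hr`,
#'   `pct_ecvp_duration` and `death_28d`.
#' @return A data.frame with one row per quartile x variable:
#'   `quartile`, `variable`, `n_survivor`, `n_nonsurvivor`,
#'   `median_survivor`, `median_nonsurvivor`, `p_value`, `flag`.
#' @export
quartile_duration_comparison <- function(data) {
  need <- c("ecvp_load", "ecvp_duration_hr", "pct_ecvp_duration", "death_28d")
  if (!all(need %in% names(data)))
    stop("need columns ", paste(need, collapse = ", "))
  br <- stats::quantile(data$ecvp_load, probs = seq(0, 1, 0.25))
  br[1] <- -Inf  # lowest quartile closed below
  q <- cut(data$ecvp_load, breaks = unique(br), right = TRUE,
           labels = FALSE)
  q <- factor(paste0("Q", q), levels = paste0("Q", sort(unique(q))))
  rows <- list()
  for (ql in levels(q)) {
    idx <- q == ql
    for (v in c("ecvp_duration_hr", "pct_ecvp_duration")) {
      surv <- data[[v]][idx & data$death_28d == 0]
      nons <- data[[v]][idx & data$death_28d == 1]
      if (length(surv) == 0L || length(nons) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          quartile = ql, variable = v,
          n_survivor = length(surv), n_nonsurvivor = length(nons),
          median_survivor = NA_real_, median_nonsurvivor = NA_real_,
          p_value = NA_real_, flag = "single_class")
        next
      }
      p <- suppressWarnings(stats::wilcox.test(surv, nons)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        quartile = ql, variable = v,
        n_survivor = length(surv), n_nonsurvivor = length(nons),
        median_survivor = stats::median(surv),
        median_nonsurvivor = stats::median(nons),
        p_value = p, flag = "ok")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "quartile") <- q
  out
}
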