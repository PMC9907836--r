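#' Render the four standard result figures
#'
#' Writes, when their inputs are available: the dose-response figure (raw
#' per-integer-bin mortality bars with the lowess curve), the Kaplan-Meier
#' figure by exposure group, the fluid-balance figure (median and IQR of
#' 72-h intake, urine output and balance by exposure group), and the
#' quartile figure (percentage of ECVP duration by ECVP-load quartile,
#' survivors vs non-survivors). A figure whose input is missing is skipped
#' with a warning.
#'
#' @param res Stage-output list as produced inside [run_pipeline()]
#'   (elements `lowess`, `km`, `data`, `quartiles` are used).
#' @param out_dir Directory for the PNG files.
#' @return Invisibly, the paths written.
#' @export
render_figures <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_fig <- function(name, plot) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, plot, width = 7, height = 5, dpi = 120)
    written <<- c(written, path)
  }

  if (is.null(res$lowess)) {
    warning("dose-response figure skipped: lowess results missing")
  } else {
    p <- ggplot2::ggplot(res$lowess$bins,
                         ggplot2::aes(x = bin, y = 100 * mortality)) +
      ggplot2::geom_col(fill = "grey70", colour = "grey30") +
      ggplot2::geom_line(data = res$lowess$smooth,
                         ggplot2::aes(x = x, y = 100 * y),
                         colour = "firebrick", linewidth = 1) +
      ggplot2::labs(x = "Normalized ECVP load (mmHg)",
                    y = "28-day mortality (%)",
                    title = "Mortality by normalized ECVP load") +
      ggplot2::theme_minimal()
    save_fig("fig_dose_response.png", p)
  }

  if (is.null(res$km)) {
    warning("survival figure skipped: Kaplan-Meier results missing")
  } else {
    cv <- res$km$curves
    base <- do.call(rbind, lapply(unique(cv$group), function(g)
      data.frame(group = g, time = 0, surv = 1)))
    cv <- rbind(base, cv[, c("group", "time", "surv")])
    p <- ggplot2::ggplot(cv, ggplot2::aes(time, surv, colour = group)) +
      ggplot2::geom_step(linewidth = 1) +
      ggplot2::coord_cartesian(ylim = c(0, 1), xlim = c(0, 28)) +
      ggplot2::labs(x = "Days from ICU admission", y = "Survival",
                    colour = "Normalized ECVP load",
                    title = sprintf("28-day survival (log-rank p = %.3g)",
                                    res$km$p_value)) +
      ggplot2::theme_minimal()
    save_fig("fig_km.png", p)
  }

  if (is.null(res$data) || !"exposure_group" %in% names(res$data) ||
      !all(c("intake_72h_ml", "urine_72h_ml") %in% names(res$data))) {
    warning("fluid figure skipped: exposure groups or fluid totals missing")
  } else {
    d <- res$data
    d$fluid_balance_72h_ml <- d$intake_72h_ml - d$urine_72h_ml
    long <- do.call(rbind, lapply(
      c("intake_72h_ml", "urine_72h_ml", "fluid_balance_72h_ml"),
      function(v) data.frame(group = d$exposure_group, variable = v,
                             value = d[[v]])))
    med <- stats::aggregate(value ~ group + variable, long, stats::median)
    q1 <- stats::aggregate(value ~ group + variable, long,
                           function(x) stats::quantile(x, 0.25))
    q3 <- stats::aggregate(value ~ group + variable, long,
                           function(x) stats::quantile(x, 0.75))
    med$lo <- q1$value; med$hi <- q3$value
    p <- ggplot2::ggplot(med, ggplot2::aes(variable, value, fill = group)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.25) +
      ggplot2::labs(x = NULL, y = "mL (median, IQR)",
                    fill = "Normalized ECVP load",
                    title = "72-hour fluid totals by exposure group") +
      ggplot2::theme_minimal()
    save_fig("fig_fluid.png", p)
  }

  if (is.null(res$quartiles) || is.null(res$data) ||
      is.null(attr(res$quartiles, "quartile"))) {
    warning("quartile figure skipped: quartile results missing")
  } else {
    d <- res$data
    d$quartile <- attr(res$quartiles, "quartile")
    d$outcome <- factor(ifelse(d$death_28d == 1, "non-survivor", "survivor"),
                        levels = c("survivor", "non-survivor"))
    p <- ggplot2::ggplot(d, ggplot2::aes(quartile, pct_ecvp_duration,
                                         fill = outcome)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = "ECVP load quartile",
                    y = "ECVP duration / CVP duration (%)",
                    fill = NULL,
                    title = "ECVP duration share by load quartile") +
      ggplot2::theme_minimal()
    save_fig("fig_quartiles.png", p)
  }
  invisible(written)
}
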