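#!/usr/bin/env Rscript
# The statistical battery: baseline comparisons, lowess dose-response,
# median-split Kaplan-Meier with log-rank, fluid/AKI comparisons between
# exposure groups, quartile subgroup analysis of ECVP duration, and the
# univariate screen followed by forward stepwise logistic regression.

library(cvpload)

d <- readRDS("results/analysis_table.rds")

baseline_vars <- c("age", "female", "weight", "sofa", "sapsii", "chf",
                   "liver_mild", "liver_severe", "renal", "diabetes",
                   "cancer", "lactate_max", "creatinine_max",
                   "hemoglobin_min", "platelet_min", "inr_max", "map_min",
                   "temp_mean", "spo2_min")

## Baseline characteristics by outcome ------------------------------------
tab1 <- baseline_table(d, "outcome_group", baseline_vars)
data.table::fwrite(tab1, "results/table_baseline.csv")

## Median split and survival ----------------------------------------------
sp <- median_split(d, "norm_ecvp_load")
d$exposure_group <- sp$group
cat(sprintf("Median split at %.2f mmHg: %d high / %d low\n",
            sp$threshold, sp$n_high, sp$n_low))

km <- km_logrank(d, d$exposure_group)
cat(sprintf("Log-rank: chisq = %.2f, p = %.4g\n", km$chisq, km$p_value))
cat(sprintf("  28-day mortality: high %.1f%%, low %.1f%%\n",
            100 * mean(d$death_28d[d$exposure_group == "high"]),
            100 * mean(d$death_28d[d$exposure_group == "low"])))
jsonlite::write_json(list(threshold = sp$threshold, chisq = km$chisq,
                          p_value = km$p_value, curves = km$curves),
                     "results/km.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)

## Dose-response -----------------------------------------------------------
lw <- lowess_mortality(d, span = 0.8)
data.table::fwrite(lw$bins, "results/lowess_bins.csv")
data.table::fwrite(lw$smooth, "results/lowess_smooth.csv")
if (length(lw$empty_bins))
  cat("Empty integer exposure bins:", paste(lw$empty_bins, collapse = ", "),
      "\n")

## Fluid balance and AKI by exposure group ---------------------------------
d$fluid_balance_72h_ml <- d$intake_72h_ml - d$urine_72h_ml
fluids <- baseline_table(d, "exposure_group",
                         c("aki", "intake_72h_ml", "urine_72h_ml",
                           "fluid_balance_72h_ml"))
data.table::fwrite(fluids, "results/table_fluids.csv")
print(fluids, digits = 3)

## Quartile subgroup analysis ----------------------------------------------
q <- quartile_duration_comparison(d)
data.table::fwrite(q, "results/table_quartiles.csv")
cat("Within-quartile ECVP duration p-values (survivor vs non-survivor):\n")
print(q[q$variable == "ecvp_duration_hr",
        c("quartile", "median_survivor", "median_nonsurvivor", "p_value")],
      digits = 3)

## Univariate screen + forward logistic ------------------------------------
screen <- univariate_screen(d, c(baseline_vars, "norm_ecvp_load"))
eligible <- screen$variable[screen$eligible]
cat(sprintf("Univariate screen: %d of %d candidates eligible (p < 0.20)\n",
            length(eligible), nrow(screen)))
fit <- forward_logistic(d, eligible)
print(fit)
tab3 <- merge(screen,
              stats::setNames(fit$terms,
                              c("variable", "or_multi", "ci_low_multi",
                                "ci_high_multi", "p_multi")),
              by = "variable", all.x = TRUE, sort = TRUE)
data.table::fwrite(tab3, "results/table_regression.csv")

if ("norm_ecvp_load" %in% fit$terms$variable) {
  r <- fit$terms[fit$terms$variable == "norm_ecvp_load", ]
  cat(sprintf(
    "Adjusted OR per mmHg normalized ECVP load: %.3f (%.3f-%.3f), p = %.3g\n",
    r$or, r$ci_low, r$ci_high, r$p_value))
}
saveRDS(list(split = sp, km = km, lowess = lw, quartiles = q,
             data = d, fit = fit), "results/stats.rds")
cat("Wrote results/table_*.csv, results/km.json, results/stats.rds\n")
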