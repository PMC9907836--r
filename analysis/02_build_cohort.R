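#!/usr/bin/env Rscript
# Apply the study's inclusion/exclusion windows to the exported cohort:
# artifact filtering (0-50 mmHg), CVP monitoring started within 24 h of
# ICU admission and continued to at least 72 h, age >= 18. Writes the
# selection flowchart counts.

library(cvpload)

inp <- ingest_cohort("results/data/cvp_events.csv",
                     "results/data/patients.csv")
cfg <- cohort_config()

events <- clean_values(inp$events, cfg)
cat(sprintf("Artifact filter dropped %d of %d measurements\n",
            attr(events, "n_dropped"), nrow(inp$events)))

sel <- select_patients(events, inp$patients, cfg)
print(sel$report)

trunc <- truncate_series(sel$events, cfg)
cat(sprintf("Truncated to <= %g h: %d measurements retained\n",
            cfg$window_hr, nrow(trunc)))

saveRDS(list(events = trunc, patients = sel$patients, report = sel$report),
        "results/cohort.rds")
jsonlite::write_json(unclass(sel$report)[1:6],
                     "results/selection_report.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("Wrote results/cohort.rds and results/selection_report.json\n")
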