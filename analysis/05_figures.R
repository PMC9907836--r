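#!/usr/bin/env Rscript
# Render the four standard figures from the saved statistical results:
# dose-response (bars + lowess), Kaplan-Meier by exposure group, fluid
# totals by group, and the quartile comparison of ECVP duration share.

library(cvpload)

res <- readRDS("results/stats.rds")
paths <- render_figures(res, "results/figures")
cat("Wrote:\n"); cat(paste(" ", paths, collapse = "\n"), "\n")
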