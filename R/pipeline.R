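#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: either a [sim_config()] (the
#' cohort is simulated) or paths to `cvp_events.csv`/`patients.csv` (a
#' user-supplied cohort is ingested), the [cohort_config()] with selection
#' windows and the ECVP threshold, smoothing options, and the output
#' directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate A [sim_config()], or `NULL` to ingest CSVs instead.
#' @param events_csv,patients_csv Input paths; required iff `simulate` is
#'   `NULL`.
#' @param cohort A [cohort_config()].
#' @param lowess_span Span for [lowess_mortality()] (default 0.8).
#' @param render_figures Write the four figure files (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, events_csv = NULL,
                       patients_csv = NULL, cohort = cohort_config(),
                       lowess_span = 0.8, render_figures = TRUE) {
  have_sim <- !is.null(simulate)
  have_paths <- !is.null(events_csv) || !is.null(patients_csv)
  if (have_sim == have_paths)
    stop("run_config: set exactly one of 'simulate' or the CSV input paths")
  if (have_sim && !inherits(simulate, "sim_config"))
    stop("run_config: 'simulate' must be a sim_config")
  if (have_paths && (is.null(events_csv) || is.null(patients_csv)))
    stop("run_config: both events_csv and patients_csv are required")
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(out_dir = out_dir, simulate = simulate,
                 events_csv = events_csv, patients_csv = patients_csv,
                 cohort = cohort, lowess_span = lowess_span,
                 render_figures = isTRUE(render_figures)),
            class = "run_config")
}

#' Run the full exposure analysis pipeline
#'
#' Executes simulate/ingest, artifact cleaning, cohort selection, window
#' truncation, exposure metrics, the statistical battery and (optionally)
#' the figures, writing every artifact under `cfg$out_dir` together with a
#' run log (seed, package versions, every convention in force) and a
#' manifest with MD5 checksums. Identical configuration and seed give a
#' checksum-identical manifest.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `manifest` (data.frame `file`, `md5`,
#'   `bytes`), `results` (the in-memory stage outputs) and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      partial <- build_manifest(out)
      write_json_file(partial, file.path(out, "manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ccfg <- cfg$cohort

  raw <- if (!is.null(cfg$simulate)) {
    stage("simulate", {
      coh <- generate_cohort(cfg$simulate, ccfg)
      export_cohort(coh, file.path(out, "data"))
      list(events = coh$events, patients = coh$patients)
    })
  } else {
    stage("ingest", ingest_cohort(cfg$events_csv, cfg$patients_csv))
  }

  cleaned <- stage("clean", suppressMessages(clean_values(raw$events, ccfg)))
  sel <- stage("select", select_patients(cleaned, raw$patients, ccfg))
  trunc <- stage("truncate", truncate_series(sel$events, ccfg))
  metrics <- stage("metrics",
                   suppressWarnings(compute_cohort_metrics(trunc, ccfg)))
  write_json_file(unclass(sel$report)[names(sel$report) != "reasons"],
                  file.path(out, "selection_report.json"))
  data.table::fwrite(metrics, file.path(out, "exposure_metrics.csv"))

  res <- stage("stats", run_stats(metrics, sel$patients, cfg))
  write_stats(res, out)

  if (cfg$render_figures)
    stage("figures", render_figures(res, out))

  log <- list(
    seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else NA,
    simulated = !is.null(cfg$simulate),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("cvpload")),
    selection = unclass(sel$report)[names(sel$report) != "reasons"],
    settings = list(
      cohort = unclass(ccfg),
      lowess_span = cfg$lowess_span,
      ecvp_classification = "segment endpoint mean strictly > threshold",
      ecvp_area = "full trapezoid area of elevated segments",
      window_boundary = "measurements at time <= window_hr kept (inclusive)",
      median_split_ties = "values equal to the median assigned to low group",
      undefined_norm_ecvp = "recorded 0, flagged, treated as low exposure",
      quartile_boundaries = "boundary values assigned to the lower quartile",
      forward_entry = "likelihood-ratio p < 0.05",
      univariate_screen = "Wald p < 0.20",
      ci = "Wald 95% on the log-odds scale"
    )
  )
  write_json_file(log, file.path(out, "run_log.json"))

  manifest <- build_manifest(out)
  write_json_file(manifest, file.path(out, "manifest.json"))
  invisible(list(manifest = manifest, results = res, out_dir = out))
}

# the statistical battery over the included cohort
run_stats <- function(metrics, patients, cfg) {
  d <- merge(patients, metrics, by = "patient_id")
  d$outcome_group <- factor(ifelse(d$death_28d == 1, "nonsurvivor",
                                   "survivor"),
                            levels = c("survivor", "nonsurvivor"))

  baseline_vars <- intersect(
    c("age", "female", "weight", "sofa", "sapsii", "chf", "liver_mild",
      "liver_severe", "renal", "diabetes", "cancer", "lactate_max",
      "creatinine_max", "hemoglobin_min", "platelet_min", "inr_max",
      "map_min", "temp_mean", "spo2_min"),
    names(d))
  exposure_vars <- c("cvp_duration_hr", "ecvp_duration_hr",
                     "pct_ecvp_duration", "cvp_load", "ecvp_load",
                     "norm_cvp_load", "norm_ecvp_load", "avg_ecvp_load")

  table1 <- baseline_table(d, "outcome_group", baseline_vars)
  table2 <- baseline_table(d, "outcome_group", exposure_vars, "continuous")

  split <- median_split(d, "norm_ecvp_load")
  d$exposure_group <- split$group
  km <- km_logrank(d, d$exposure_group)
  lw <- lowess_mortality(d, span = cfg$lowess_span)
  quart <- quartile_duration_comparison(d)

  d$fluid_balance_72h_ml <- d$intake_72h_ml - d$urine_72h_ml
  fluid_vars <- intersect(c("aki", "intake_72h_ml", "urine_72h_ml",
                            "fluid_balance_72h_ml"), names(d))
  group_tbl <- baseline_table(d, "exposure_group", fluid_vars)

  screen <- univariate_screen(d, c(baseline_vars, "norm_ecvp_load"))
  eligible <- screen$variable[screen$eligible]
  multi <- forward_logistic(d, eligible)

  list(data = d, table1 = table1, table2 = table2, split = split, km = km,
       lowess = lw, quartiles = quart, group_table = group_tbl,
       univariate = screen, multivariate = multi)
}

write_stats <- function(res, out) {
  data.table::fwrite(res$table1, file.path(out, "table1.csv"))
  data.table::fwrite(res$table2, file.path(out, "table2.csv"))
  tab3 <- merge(res$univariate,
                stats::setNames(res$multivariate$terms,
                                c("variable", "or_multi", "ci_low_multi",
                                  "ci_high_multi", "p_multi")),
                by = "variable", all.x = TRUE, sort = TRUE)
  data.table::fwrite(tab3, file.path(out, "table3.csv"))
  data.table::fwrite(res$quartiles, file.path(out, "quartiles.csv"))
  data.table::fwrite(res$group_table, file.path(out, "exposure_groups.csv"))
  lw <- merge(res$lowess$bins,
              data.frame(bin = round(res$lowess$smooth$x),
                         smoothed = res$lowess$smooth$y),
              by = "bin")
  lw <- stats::aggregate(cbind(n, mortality, smoothed) ~ bin, lw, mean)
  data.table::fwrite(lw, file.path(out, "lowess.csv"))
  write_json_file(list(threshold = res$split$threshold,
                       n_high = res$split$n_high, n_low = res$split$n_low,
                       chisq = res$km$chisq, p_value = res$km$p_value,
                       flag = res$km$flag, curves = res$km$curves),
                  file.path(out, "km.json"))
}

build_manifest <- function(out_dir) {
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE, full.names = FALSE),
    "manifest.json"))
  paths <- file.path(out_dir, files)
  data.frame(file = files,
             md5 = unname(tools::md5sum(paths)),
             bytes = unname(file.size(paths)))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}
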