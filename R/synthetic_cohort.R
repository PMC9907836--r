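#' Configuration for the synthetic ICU cohort generator
#'
#' Generative parameters for a seeded synthetic sepsis cohort whose
#' statistical structure matches what the exposure analysis assumes:
#' irregular CVP sampling over the first days of ICU stay, patient-level
#' CVP setpoints with mean-reverting autocorrelated fluctuation
#' (Ornstein-Uhlenbeck), a logistic 28-day mortality link on normalized
#' ECVP load plus age and SAPS-II, urine output decreasing and fluid
#' balance increasing with ECVP exposure, and an AKI probability increasing
#' with exposure.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer RNG seed; identical config + seed gives a
#'   bit-identical cohort.
#' @param sampling_mean_interval_hr Mean gap between scheduled CVP
#'   measurements, hours (exponential gaps; default 1).
#' @param sampling_dropout_prob Probability that a scheduled measurement is
#'   missing from the chart (default 0.15).
#' @param monitoring_end_hr Length-2 range; each patient's monitoring end
#'   is uniform on this interval, hours (default `c(72, 96)`).
#' @param start_window_hr Monitoring start is uniform on
#'   `[0, start_window_hr]` hours from ICU admission (default 24).
#' @param cvp_setpoint_mean,cvp_setpoint_sd Population distribution of the
#'   patient-level CVP setpoint, mmHg (defaults 13 and 4).
#' @param cvp_ou_sd Stationary SD of the Ornstein-Uhlenbeck fluctuation
#'   around the setpoint, mmHg (default 2).
#' @param cvp_ou_tau_hr Ornstein-Uhlenbeck relaxation time, hours (default
#'   6): elevated episodes are temporally clustered on this scale.
#' @param beta0 Logit intercept of the mortality model. The default `NULL`
#'   solves the intercept on the realized linear predictors so that the
#'   expected marginal 28-day mortality equals `target_mortality`, keeping
#'   the cohort realistic under any effect-size override.
#' @param target_mortality Marginal 28-day mortality used when `beta0` is
#'   `NULL` (default 0.398).
#' @param beta_ecvp Log-odds of 28-day death per mmHg of normalized ECVP
#'   load (default `log(1.058)`).
#' @param beta_age,beta_sapsii Covariate log-odds per year / per SAPS-II
#'   point (defaults `log(1.02)`, `log(1.018)`).
#' @param urine_base,urine_slope,urine_sd 72-h urine output model, mL:
#'   `base + slope * normalized ECVP load + Normal(0, sd)`, floored at 0;
#'   `urine_slope` is negative (default -400 mL per mmHg).
#' @param intake_meanlog,intake_sdlog Log-normal 72-h fluid intake, mL.
#' @param aki_beta0,aki_beta Logistic AKI model: intercept and log-odds per
#'   mmHg of normalized ECVP load.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1100,
                       seed = 1L,
                       sampling_mean_interval_hr = 1.0,
                       sampling_dropout_prob = 0.15,
                       monitoring_end_hr = c(72, 96),
                       start_window_hr = 24,
                       cvp_setpoint_mean = 13.0,
                       cvp_setpoint_sd = 4.0,
                       cvp_ou_sd = 2.0,
                       cvp_ou_tau_hr = 6.0,
                       beta0 = NULL,
                       target_mortality = 0.398,
                       beta_ecvp = log(1.058),
                       beta_age = log(1.02),
                       beta_sapsii = log(1.018),
                       urine_base = 9500,
                       urine_slope = -400,
                       urine_sd = 2200,
                       intake_meanlog = log(4000),
                       intake_sdlog = 0.85,
                       aki_beta0 = -2.8,
                       aki_beta = 0.33) {
  cfg <- as.list(environment())
  num_scalar <- setdiff(names(cfg), c("beta0", "monitoring_end_hr", "seed"))
  for (f in num_scalar) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("sim_config: field '", f, "' must be a finite numeric scalar")
  }
  if (cfg$n_patients < 1) stop("sim_config: n_patients must be >= 1")
  if (cfg$sampling_mean_interval_hr <= 0)
    stop("sim_config: sampling_mean_interval_hr must be > 0")
  if (cfg$sampling_dropout_prob < 0 || cfg$sampling_dropout_prob > 1)
    stop("sim_config: sampling_dropout_prob must be in [0, 1]")
  if (length(cfg$monitoring_end_hr) != 2L ||
      any(!is.finite(cfg$monitoring_end_hr)) ||
      cfg$monitoring_end_hr[1] > cfg$monitoring_end_hr[2] ||
      cfg$monitoring_end_hr[1] <= 0)
    stop("sim_config: monitoring_end_hr must be an increasing positive range")
  for (f in c("cvp_setpoint_sd", "cvp_ou_sd", "cvp_ou_tau_hr", "urine_sd"))
    if (cfg[[f]] <= 0) stop("sim_config: field '", f, "' must be > 0")
  if (cfg$target_mortality <= 0 || cfg$target_mortality >= 1)
    stop("sim_config: target_mortality must be in (0, 1)")
  if (!is.null(cfg$beta0) &&
      (!is.numeric(cfg$beta0) || length(cfg$beta0) != 1L))
    stop("sim_config: beta0 must be NULL or a numeric scalar")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_patients <- as.integer(cfg$n_patients)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Keys map 1:1 onto [sim_config()] arguments; absent keys take the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown sim_config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Generate a synthetic sepsis cohort
#'
#' Simulates each patient's irregular CVP stream and covariates, then draws
#' 28-day death from a logistic model on the normalized ECVP load *as the
#' pipeline itself measures it* (computed with [compute_cohort_metrics()]
#' on the stream truncated to the analysis window), so the generative
#' estimand and the pipeline estimand agree by construction.
#'
#' Measurement times are cumulative exponential gaps from a uniform start
#' on `[0, start_window_hr]` until the patient's monitoring end, each
#' scheduled measurement independently dropped with
#' `sampling_dropout_prob`. CVP values follow a discretized
#' Ornstein-Uhlenbeck process around a patient-level setpoint, floored at
#' 0 and charted to 0.1 mmHg. Deaths get a survival time uniform on
#' (0, 28] days; survivors are censored at 28 days.
#'
#' @param cfg A [sim_config()].
#' @param cohort_cfg A [cohort_config()]; defines the truncation window and
#'   ECVP threshold used for the latent exposure entering the outcome
#'   model.
#'
#' @return A list of class `synthetic_cohort`: `events` (long CVP table),
#'   `patients` (one row per patient, the full covariate/outcome table) and
#'   `truth` (per-patient latent normalized ECVP load, linear predictor and
#'   death probability, plus the config), suitable for [export_cohort()].
#' @export
generate_cohort <- function(cfg = sim_config(), cohort_cfg = cohort_config()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(cohort_cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  ## measurement schedule -------------------------------------------------
  t_start <- stats::runif(n, 0, cfg$start_window_hr)
  t_end <- stats::runif(n, cfg$monitoring_end_hr[1], cfg$monitoring_end_hr[2])
  m <- ceiling(cfg$monitoring_end_hr[2] / cfg$sampling_mean_interval_hr * 1.6) + 30
  gaps <- matrix(stats::rexp(m * n, rate = 1 / cfg$sampling_mean_interval_hr),
                 nrow = m)
  gaps[1L, ] <- 0  # first scheduled measurement at monitoring start
  tm <- apply(gaps, 2L, cumsum)
  tm <- sweep(tm, 2L, t_start, "+")

  ## Ornstein-Uhlenbeck CVP around a patient setpoint ---------------------
  setp <- stats::rnorm(n, cfg$cvp_setpoint_mean, cfg$cvp_setpoint_sd)
  phi <- exp(-gaps / cfg$cvp_ou_tau_hr)
  z <- matrix(stats::rnorm(m * n), nrow = m)
  v <- matrix(0, nrow = m, ncol = n)
  v_prev <- setp + cfg$cvp_ou_sd * z[1L, ]  # stationary initial draw
  v[1L, ] <- v_prev
  for (i in 2:m) {
    v_prev <- setp + phi[i, ] * (v_prev - setp) +
      cfg$cvp_ou_sd * sqrt(1 - phi[i, ]^2) * z[i, ]
    v[i, ] <- v_prev
  }
  v <- round(pmax(v, 0), 1)

  keep <- tm <= rep(t_end, each = m) &
    matrix(stats::runif(m * n) >= cfg$sampling_dropout_prob, nrow = m)
  events <- data.frame(
    patient_id = rep(ids, times = colSums(keep)),
    time_hr = tm[keep],            # column-major: grouped by patient,
    cvp_mmhg = v[keep]             # increasing time within patient
  )

  ## covariates ------------------------------------------------------------
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  patients <- data.frame(
    patient_id = ids,
    age = round(cl(stats::rnorm(n, 66, 15.3), 18, 95)),
    female = stats::rbinom(n, 1, 0.42),
    weight = round(cl(stats::rnorm(n, 84.7, 25), 35, 250), 1),
    sofa = round(cl(stats::rnorm(n, 9.1, 3.6), 0, 24)),
    sapsii = round(cl(stats::rnorm(n, 51.6, 14.3), 6, 120)),
    chf = stats::rbinom(n, 1, 0.43),
    liver_mild = stats::rbinom(n, 1, 0.261),
    liver_severe = stats::rbinom(n, 1, 0.108),
    renal = stats::rbinom(n, 1, 0.294),
    diabetes = stats::rbinom(n, 1, 0.289),
    cancer = stats::rbinom(n, 1, 0.119),
    lactate_max = round(cl(stats::rnorm(n, 4.1, 3.2), 0.4, 30), 1),
    creatinine_max = round(cl(stats::rnorm(n, 2.2, 1.6), 0.2, 15), 1),
    hemoglobin_min = round(cl(stats::rnorm(n, 9.3, 2.1), 3, 18), 1),
    platelet_min = round(cl(stats::rnorm(n, 184.5, 132.2), 5, 900)),
    inr_max = round(cl(stats::rnorm(n, 2.1, 1.4), 0.8, 12), 1),
    map_min = round(cl(stats::rnorm(n, 48.1, 14.4), 20, 100)),
    temp_mean = round(stats::rnorm(n, 36.9, 0.8), 1),
    spo2_min = round(cl(stats::rnorm(n, 89.6, 9.4), 40, 100))
  )

  ## latent exposure as the pipeline measures it --------------------------
  trunc_events <- truncate_series(events, cohort_cfg)
  metr <- suppressWarnings(compute_cohort_metrics(trunc_events, cohort_cfg))
  necvp <- stats::setNames(rep(0, n), ids)  # degenerate series: no exposure
  necvp[metr$patient_id] <- metr$norm_ecvp_load

  ## outcomes --------------------------------------------------------------
  lin <- cfg$beta_ecvp * necvp + cfg$beta_age * patients$age +
    cfg$beta_sapsii * patients$sapsii
  beta0 <- cfg$beta0
  if (is.null(beta0)) {
    beta0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + lin)) - cfg$target_mortality,
      interval = c(-60, 60), tol = 1e-10
    )$root
  }
  p_death <- stats::plogis(beta0 + lin)
  death <- stats::rbinom(n, 1, p_death)
  surv_days <- ifelse(death == 1, stats::runif(n, 0, 28), 28)

  urine <- round(pmax(
    cfg$urine_base + cfg$urine_slope * necvp + stats::rnorm(n, 0, cfg$urine_sd),
    0))
  intake <- round(stats::rlnorm(n, cfg$intake_meanlog, cfg$intake_sdlog))
  p_aki <- stats::plogis(cfg$aki_beta0 + cfg$aki_beta * necvp)

  patients$intake_72h_ml <- intake
  patients$urine_72h_ml <- urine
  patients$aki <- stats::rbinom(n, 1, p_aki)
  patients$death_28d <- death
  # floor at 0.001 d so charting precision cannot produce a zero time
  patients$survival_days <- pmax(round(surv_days, 3), 0.001)

  truth <- data.frame(patient_id = ids, norm_ecvp_load = unname(necvp),
                      linear_predictor = beta0 + lin, p_death = p_death,
                      p_aki = p_aki)
  cfg$beta0_used <- beta0
  structure(list(events = events, patients = patients, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d patients, %d CVP measurements, ",
                     "28-day mortality %.1f%%\n"),
              nrow(x$patients), nrow(x$events),
              100 * mean(x$patients$death_28d)))
  invisible(x)
}

#' Write a synthetic cohort to CSV
#'
#' Writes `cvp_events.csv` (`patient_id,time_hr,cvp_mmhg`) and
#' `patients.csv` (one row per patient) in the layout [ingest_cohort()]
#' reads back, with full numeric precision so the round trip is exact.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param directory Output directory, created if needed.
#' @return Invisibly, the two file paths written.
#' @export
export_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (nrow(cohort$patients) == 0L || nrow(cohort$events) == 0L)
    stop("refusing to export an empty cohort; nothing written")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(events = file.path(directory, "cvp_events.csv"),
             patients = file.path(directory, "patients.csv"))
  data.table::fwrite(cohort$events, paths["events"])
  data.table::fwrite(cohort$patients, paths["patients"])
  invisible(paths)
}
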