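# Independent oracles, written before the package implementation and kept
# deliberately naive: plain loops, no shared code with R/.

# Loop-based trapezoid calculus over one series. Classifies each
# inter-measurement interval by its endpoint-mean (strict > threshold) and
# accumulates full trapezoid areas.
oracle_metrics <- function(times, values, threshold = 10) {
  stopifnot(length(times) >= 2, length(times) == length(values))
  cvp_load <- 0; ecvp_load <- 0; ecvp_dur <- 0
  for (i in seq_len(length(times) - 1)) {
    dt <- times[i + 1] - times[i]
    m <- (values[i] + values[i + 1]) / 2
    a <- m * dt
    cvp_load <- cvp_load + a
    if (m > threshold) {
      ecvp_load <- ecvp_load + a
      ecvp_dur <- ecvp_dur + dt
    }
  }
  cvp_dur <- times[length(times)] - times[1]
  list(
    cvp_load = cvp_load,
    cvp_duration = cvp_dur,
    ecvp_load = ecvp_load,
    ecvp_duration = ecvp_dur,
    norm_cvp_load = cvp_load / cvp_dur,
    norm_ecvp_load = if (ecvp_dur > 0) ecvp_load / ecvp_dur else 0,
    avg_ecvp_load = ecvp_load / cvp_dur,
    pct_ecvp_duration = 100 * ecvp_dur / cvp_dur
  )
}

# Area under the piecewise-linear interpolant by fine-grid trapezoid
# integration on a refinement that contains every knot (exact for a
# piecewise-linear function, up to floating point).
oracle_fine_grid_auc <- function(times, values, n_grid = 4001) {
  g <- sort(unique(c(times, seq(min(times), max(times), length.out = n_grid))))
  v <- approx(times, values, xout = g)$y
  sum((v[-1] + v[-length(v)]) / 2 * diff(g))
}

# Pearson chi-square statistic for a 2x2 table, from the definition.
oracle_chisq_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Hand-worked expectations, frozen from the oracle above:
#   times [0,1,3], values [12,14,8]:
#     segment 1: mean 13 > 10, area 13, len 1
#     segment 2: mean 11 > 10, area 22, len 2
#     cvp_load 35, cvp_duration 3, ecvp_load 35, ecvp_duration 3,
#     norm_ecvp_load 35/3, pct 100
#   times [0,1,2,3], values [12,14,4,4]:
#     segment means 13, 9, 4; areas 13, 9, 4
#     cvp_load 26; only segment 1 elevated: ecvp_load 13, ecvp_duration 1,
#     norm_ecvp_load 13, avg_ecvp_load 13/3, pct 100/3
hand_cases <- list(
  list(
    times = c(0, 1, 3), values = c(12, 14, 8),
    cvp_load = 35, cvp_duration = 3, ecvp_load = 35, ecvp_duration = 3,
    norm_cvp_load = 35 / 3, norm_ecvp_load = 35 / 3,
    avg_ecvp_load = 35 / 3, pct_ecvp_duration = 100
  ),
  list(
    times = c(0, 1, 2, 3), values = c(12, 14, 4, 4),
    cvp_load = 26, cvp_duration = 3, ecvp_load = 13, ecvp_duration = 1,
    norm_cvp_load = 26 / 3, norm_ecvp_load = 13,
    avg_ecvp_load = 13 / 3, pct_ecvp_duration = 100 / 3
  )
)

# Random irregular series for property tests.
random_series <- function(n = NULL, t_max = 72) {
  if (is.null(n)) n <- sample(2:120, 1)
  times <- sort(runif(n, 0, t_max))
  while (any(diff(times) <= 0)) times <- sort(runif(n, 0, t_max))
  values <- pmax(rnorm(n, mean = runif(1, 4, 16), sd = runif(1, 0.5, 5)), 0)
  list(times = times, values = values)
}
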