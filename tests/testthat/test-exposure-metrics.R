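# Trapezoidal exposure calculus: hand-worked oracles, then properties.

test_that("hand-worked trapezoid examples match the independent oracle", {
  for (case in hand_cases) {
    s <- cvp_series("P1", case$times, case$values)
    m <- compute_metrics(s)
    o <- oracle_metrics(case$times, case$values)
    # oracle agrees with its own frozen arithmetic
    expect_equal(o$cvp_load, case$cvp_load)
    expect_equal(o$ecvp_load, case$ecvp_load)
    # implementation against frozen values
    expect_equal(m$cvp_load, case$cvp_load)
    expect_equal(m$cvp_duration_hr, case$cvp_duration)
    expect_equal(m$ecvp_load, case$ecvp_load)
    expect_equal(m$ecvp_duration_hr, case$ecvp_duration)
    expect_equal(m$norm_cvp_load, case$norm_cvp_load)
    expect_equal(m$norm_ecvp_load, case$norm_ecvp_load)
    expect_equal(m$avg_ecvp_load, case$avg_ecvp_load)
    expect_equal(m$pct_ecvp_duration, case$pct_ecvp_duration)
    expect_true(m$norm_ecvp_defined)
  }
})

test_that("segment classification uses the strict > threshold rule", {
  # endpoint mean exactly 10 is not elevated
  seg <- build_segments(cvp_series("P1", c(0, 2), c(8, 12)), threshold = 10)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$mean_cvp, 10)
  expect_false(seg$is_ecvp)

  seg2 <- build_segments(cvp_series("P2", c(0, 1, 3), c(12, 14, 8)))
  expect_equal(seg2$mean_cvp, c(13, 11))
  expect_equal(seg2$area, c(13, 22))
  expect_true(all(seg2$is_ecvp))

  # constant series at the threshold: no elevated segment anywhere
  grid <- seq(0, 72, by = 3)
  segc <- build_segments(cvp_series("P3", grid, rep(10, length(grid))))
  expect_false(any(segc$is_ecvp))
})

test_that("constant sub-threshold series yields flagged-zero ECVP metrics", {
  grid <- seq(0, 72, length.out = 25)
  m <- compute_metrics(cvp_series("P1", grid, rep(8, 25)))
  expect_equal(m$norm_cvp_load, 8)
  expect_equal(m$ecvp_load, 0)
  expect_equal(m$ecvp_duration_hr, 0)
  expect_equal(m$norm_ecvp_load, 0)
  expect_false(m$norm_ecvp_defined)
  expect_equal(m$pct_ecvp_duration, 0)
})

test_that("degenerate series (< 2 measurements) error names the patient", {
  s <- cvp_series("P77", 5, 12)
  expect_error(compute_metrics(s), "P77")
  expect_error(build_segments(s), "P77")
})

test_that("random series match the oracle and satisfy the invariants", {
  set.seed(101)
  for (i in 1:50) {
    rs <- random_series()
    s <- cvp_series("PX", rs$times, rs$values)
    m <- compute_metrics(s)
    o <- oracle_metrics(rs$times, rs$values)
    expect_equal(m$cvp_load, o$cvp_load, tolerance = 1e-12)
    expect_equal(m$ecvp_load, o$ecvp_load, tolerance = 1e-12)
    expect_equal(m$ecvp_duration_hr, o$ecvp_duration, tolerance = 1e-12)

    # structural invariants
    expect_lte(m$ecvp_duration_hr, m$cvp_duration_hr + 1e-12)
    expect_lte(m$ecvp_load, m$cvp_load + 1e-9)
    expect_gte(m$pct_ecvp_duration, 0)
    expect_lte(m$pct_ecvp_duration, 100 + 1e-12)
    expect_lte(m$avg_ecvp_load, m$norm_cvp_load + 1e-12)
    expect_lte(m$avg_ecvp_load, m$norm_ecvp_load + 1e-12)
    if (m$norm_ecvp_defined) expect_gt(m$norm_ecvp_load, 10)

    # exact decomposition into elevated and non-elevated areas
    seg <- build_segments(s)
    expect_identical(m$cvp_load,
                     sum(seg$area[seg$is_ecvp]) + sum(seg$area[!seg$is_ecvp]))
  }
})

test_that("ECVP load and duration are non-increasing in the threshold", {
  set.seed(202)
  for (i in 1:20) {
    rs <- random_series(n = 60)
    s <- cvp_series("PX", rs$times, rs$values)
    thresholds <- c(4, 8, 10, 12, 16)
    loads <- vapply(thresholds, function(th) compute_metrics(s, th)$ecvp_load, 0)
    durs <- vapply(thresholds,
                   function(th) compute_metrics(s, th)$ecvp_duration_hr, 0)
    expect_true(all(diff(loads) <= 1e-12))
    expect_true(all(diff(durs) <= 1e-12))
  }
})

test_that("metrics are time-shift invariant and scale linearly in time", {
  set.seed(303)
  rs <- random_series(n = 40)
  s <- cvp_series("PX", rs$times, rs$values)
  m <- compute_metrics(s)

  shifted <- compute_metrics(cvp_series("PX", rs$times + 13.7, rs$values))
  for (f in c("cvp_load", "ecvp_load", "cvp_duration_hr", "ecvp_duration_hr",
              "norm_cvp_load", "norm_ecvp_load", "avg_ecvp_load",
              "pct_ecvp_duration"))
    expect_equal(shifted[[f]], m[[f]], tolerance = 1e-9)

  k <- 2.5
  scaled <- compute_metrics(cvp_series("PX", rs$times * k, rs$values))
  expect_equal(scaled$cvp_load, k * m$cvp_load, tolerance = 1e-9)
  expect_equal(scaled$ecvp_load, k * m$ecvp_load, tolerance = 1e-9)
  expect_equal(scaled$cvp_duration_hr, k * m$cvp_duration_hr)
  expect_equal(scaled$ecvp_duration_hr, k * m$ecvp_duration_hr,
               tolerance = 1e-9)
  expect_equal(scaled$norm_cvp_load, m$norm_cvp_load, tolerance = 1e-9)
  expect_equal(scaled$norm_ecvp_load, m$norm_ecvp_load, tolerance = 1e-9)
})

test_that("cohort metrics table matches per-series computation and is
           order-invariant", {
  set.seed(404)
  series <- lapply(1:3, function(i) random_series(n = 30))
  events <- do.call(rbind, lapply(seq_along(series), function(i)
    data.frame(patient_id = paste0("P", i), time_hr = series[[i]]$times,
               cvp_mmhg = series[[i]]$values)))
  tab <- compute_cohort_metrics(events)
  expect_equal(nrow(tab), 3L)
  for (i in 1:3) {
    m <- compute_metrics(cvp_series(paste0("P", i), series[[i]]$times,
                                    series[[i]]$values))
    row <- tab[tab$patient_id == paste0("P", i), ]
    expect_equal(row$cvp_load, m$cvp_load)
    expect_equal(row$norm_ecvp_load, m$norm_ecvp_load)
    expect_equal(row$pct_ecvp_duration, m$pct_ecvp_duration)
  }
  perm <- events[sample(nrow(events)), ]
  expect_equal(compute_cohort_metrics(perm), tab,
               ignore_attr = "failures")
})

test_that("cohort metrics report degenerate patients and keep the rest", {
  events <- rbind(
    data.frame(patient_id = "A", time_hr = c(0, 1, 2), cvp_mmhg = c(9, 11, 12)),
    data.frame(patient_id = "B", time_hr = 5, cvp_mmhg = 14),
    data.frame(patient_id = "C", time_hr = c(0, 3), cvp_mmhg = c(6, 7)))
  expect_warning(tab <- compute_cohort_metrics(events), "B")
  expect_equal(tab$patient_id, c("A", "C"))
  expect_equal(attr(tab, "failures"), "B")
})
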