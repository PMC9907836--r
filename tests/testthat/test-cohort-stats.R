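# Statistical battery: normality, comparisons, splits, survival, lowess,
# logistic screening and forward selection.

test_that("normality assessment distinguishes clear cases", {
  set.seed(1)
  expect_true(assess_normality(rnorm(500))$normal)
  expect_false(assess_normality(rexp(500))$normal)
  cst <- assess_normality(rep(3.2, 50))
  expect_false(cst$normal)
  expect_equal(cst$flag, "degenerate_sd")
  small <- assess_normality(rnorm(5))
  expect_false(small$normal)
  expect_equal(small$flag, "small_sample")
})

test_that("compare_groups picks the test by type and normality", {
  set.seed(2)
  n <- 200
  d <- data.frame(
    g = rep(c("a", "b"), each = n),
    gauss = c(rnorm(n, 10, 2), rnorm(n, 10, 2)),
    skewed = c(rexp(n), rexp(n)),
    flag = rbinom(2 * n, 1, 0.5))
  expect_equal(compare_groups(d, "g", "gauss")$test, "t")
  expect_equal(compare_groups(d, "g", "skewed")$test, "wilcoxon")
  expect_equal(compare_groups(d, "g", "flag")$test, "chisq")

  # identical balanced binary split: no association
  d2 <- data.frame(g = rep(c("a", "b"), each = 100),
                   flag = rep(c(0, 1), times = 100))
  expect_gt(compare_groups(d2, "g", "flag")$p_value, 0.99)

  # a large shift is detected by both continuous branches
  d$shifted <- d$gauss + ifelse(d$g == "b", 50, 0)
  expect_lt(compare_groups(d, "g", "shifted")$p_value, 1e-10)
  d$shifted_sk <- d$skewed + ifelse(d$g == "b", 50, 0)
  expect_lt(compare_groups(d, "g", "shifted_sk")$p_value, 1e-10)

  # zero-variance continuous variable falls back to wilcoxon
  d$const_a <- ifelse(d$g == "a", 1, rnorm(2 * n))
  r <- compare_groups(d, "g", "const_a", type = "continuous")
  expect_equal(r$test, "wilcoxon")
  expect_match(r$flag, "zero_variance")

  expect_error(compare_groups(d[d$g == "a", ], "g", "gauss"), "2 levels")
})

test_that("chi-square on a 2x2 agrees with the hand-computed Pearson
           statistic", {
  # counts reconstructed from AKI incidences 92.9% of 550 vs 82.3% of 521
  a <- round(0.929 * 550); b <- 550 - a
  c <- round(0.823 * 521); d_ <- 521 - c
  o <- oracle_chisq_2x2(a, b, c, d_)
  df <- data.frame(
    g = rep(c("high", "low"), c(550, 521)),
    aki = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d_)))
  r <- compare_groups(df, "g", "aki")
  expect_equal(r$statistic, o$stat, tolerance = 1e-9)
  expect_equal(r$p_value, o$p, tolerance = 1e-9)
  expect_lt(r$p_value, 0.001)
})

test_that("median split honors the >-median rule and ties go low", {
  m1 <- data.frame(norm_ecvp_load = c(1, 2, 3, 4))
  s1 <- median_split(m1)
  expect_equal(s1$threshold, 2.5)
  expect_equal(as.character(s1$group), c("low", "low", "high", "high"))

  # tie rule by enumeration: median 2, only the 3 is high
  m2 <- data.frame(norm_ecvp_load = c(1, 2, 2, 3))
  s2 <- median_split(m2)
  expect_equal(s2$threshold, 2)
  expect_equal(s2$n_high, 1L)
  expect_equal(s2$n_low, 3L)
  expect_equal(s2$n_high + s2$n_low, 4L)

  expect_error(median_split(data.frame(norm_ecvp_load = rep(5, 10))),
               "identical")
})

test_that("median split is deterministic across regenerated cohorts", {
  m <- function() {
    coh <- generate_cohort(sim_config(n_patients = 150, seed = 77))
    sel <- select_patients(coh$events, coh$patients)
    suppressWarnings(compute_cohort_metrics(truncate_series(sel$events)))
  }
  expect_identical(median_split(m())$group, median_split(m())$group)
})

test_that("Kaplan-Meier machinery handles edge and extreme cases", {
  # no deaths: both curves stay at 1, p reported as 1 with a flag
  rec <- data.frame(survival_days = rep(28, 40), death_28d = 0)
  grp <- rep(c("low", "high"), 20)
  km <- km_logrank(rec, grp)
  expect_true(all(km$curves$surv == 1))
  expect_equal(km$p_value, 1)
  expect_equal(km$flag, "no_events")

  # maximal separation: one group all dies on day 1
  rec2 <- data.frame(survival_days = c(rep(1, 50), rep(28, 50)),
                     death_28d = c(rep(1, 50), rep(0, 50)))
  grp2 <- rep(c("a", "b"), each = 50)
  km2 <- km_logrank(rec2, grp2)
  expect_lt(km2$p_value, 1e-10)

  expect_error(km_logrank(rec2, rep("a", 100)), "two non-empty groups")
  bad <- data.frame(survival_days = c(0, 5), death_28d = c(1, 0))
  expect_error(km_logrank(bad, c("a", "b")), "survival_days")
})

test_that("KM at 28 days equals 1 - observed mortality without early
           censoring", {
  coh <- generate_cohort(sim_config(n_patients = 400, seed = 31))
  d <- coh$patients
  grp <- factor(ifelse(seq_len(nrow(d)) %% 2 == 0, "a", "b"))
  km <- km_logrank(d, grp)
  for (g in c("a", "b")) {
    cv <- km$curves[km$curves$group == g, ]
    expect_equal(min(cv$surv), 1 - mean(d$death_28d[grp == g]),
                 tolerance = 1e-12)
  }
  expect_true(all(tapply(km$curves$surv, km$curves$group,
                         function(s) all(diff(s) <= 0))))
})

test_that("lowess dose-response is flat under the null and monotone under a
           linear link", {
  set.seed(3)
  n <- 8000
  load <- runif(n, 8, 22)
  d0 <- data.frame(norm_ecvp_load = load,
                   death_28d = rbinom(n, 1, 0.35))
  lw0 <- lowess_mortality(d0)
  # flat within 2 percentage points of the overall rate, away from the
  # smoother's high-variance extreme edges
  inb <- lw0$smooth$x >= 9 & lw0$smooth$x <= 21
  expect_true(all(abs(lw0$smooth$y[inb] - lw0$overall_rate) < 0.02))

  p <- (load - 8) / 28  # linear in exposure
  d1 <- data.frame(norm_ecvp_load = load, death_28d = rbinom(n, 1, p))
  lw1 <- lowess_mortality(d1)
  ctr <- lw1$bins$bin
  sm_at_bin <- approx(lw1$smooth$x, lw1$smooth$y, xout = ctr, rule = 2)$y
  expect_gt(cor(ctr, sm_at_bin, method = "spearman"), 0.95)

  # too few populated bins is an error mentioning bins
  d2 <- data.frame(norm_ecvp_load = rep(12, 100),
                   death_28d = rbinom(100, 1, 0.3))
  expect_error(lowess_mortality(d2), "bins")
  expect_error(lowess_mortality(d0, span = 0), "span")
})

test_that("lowess reports empty integer bins inside the observed range", {
  d <- data.frame(norm_ecvp_load = c(rep(10, 30), rep(11, 30), rep(13, 30),
                                     rep(14, 30), rep(15, 30)),
                  death_28d = rbinom(150, 1, 0.4))
  lw <- lowess_mortality(d)
  expect_equal(lw$empty_bins, 12L)
})

test_that("univariate screening flags eligibility, separation and constants", {
  set.seed(4)
  n <- 800
  d <- data.frame(
    strong = rnorm(n),
    noise = rnorm(n),
    konst = rep(1, n))
  d$death_28d <- rbinom(n, 1, plogis(-0.5 + 1 * d$strong))
  d$sep <- d$death_28d  # predictor identical to outcome
  res <- suppressWarnings(
    univariate_screen(d, c("strong", "noise", "konst", "sep")))
  expect_true(res$eligible[res$variable == "strong"])
  expect_equal(res$flag[res$variable == "konst"], "constant")
  expect_equal(res$flag[res$variable == "sep"], "separation")
  expect_false(res$eligible[res$variable == "sep"])
  ok <- res[res$flag == "ok", ]
  expect_true(all(ok$ci_low <= ok$or & ok$or <= ok$ci_high))
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
})

test_that("forward selection finds the true predictor and resists
           duplicates", {
  set.seed(5)
  n <- 1500
  d <- data.frame(x = rnorm(n))
  d$death_28d <- rbinom(n, 1, plogis(-0.6 + log(2) * d$x))
  d$x_copy <- d$x
  d$n1 <- rnorm(n); d$n2 <- rnorm(n)
  fit <- forward_logistic(d, c("x", "x_copy", "n1", "n2"))
  expect_true("x" %in% fit$entered || "x_copy" %in% fit$entered)
  # the duplicate adds no likelihood, so exactly one of the pair enters
  expect_equal(sum(c("x", "x_copy") %in% fit$entered), 1L)
  expect_true(all(fit$terms$ci_low <= fit$terms$or))
  expect_true(all(fit$terms$or <= fit$terms$ci_high))

  empty <- forward_logistic(d, character())
  expect_equal(nrow(empty$terms), 0L)
  expect_equal(empty$flag, "no_candidates")

  # pure noise rarely enters at p_enter = 0.05; with a strict gate, never
  none <- forward_logistic(d, c("n1", "n2"), p_enter = 1e-12)
  expect_equal(none$flag, "no_entry")
})

test_that("fit_logistic recovers a known coefficient", {
  set.seed(6)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$death_28d <- rbinom(n, 1, plogis(-0.4 + 0.7 * d$x))
  r <- fit_logistic(d, "x")
  expect_equal(r$estimate, 0.7, tolerance = 0.1)
  expect_true(attr(r, "converged"))
})

test_that("quartile comparison conventions: boundaries low, degenerate
           flags, order invariance", {
  set.seed(7)
  n <- 400
  d <- data.frame(
    ecvp_load = runif(n, 0, 900),
    ecvp_duration_hr = runif(n, 0, 70),
    pct_ecvp_duration = runif(n, 0, 100),
    death_28d = rbinom(n, 1, 0.4))
  q <- quartile_duration_comparison(d)
  expect_equal(nrow(q), 8L)
  expect_true(all(q$p_value >= 0 & q$p_value <= 1, na.rm = TRUE))
  asg <- attr(q, "quartile")
  expect_equal(as.integer(table(asg)), rep(100L, 4))
  # values exactly at the quartile boundaries sit in the lower quartile:
  # for loads 1..9 the 25/50/75th percentiles are exactly 3, 5, 7
  d2 <- data.frame(ecvp_load = 1:9, ecvp_duration_hr = 1:9,
                   pct_ecvp_duration = 1:9,
                   death_28d = rep(c(0, 1), length.out = 9))
  q2 <- quartile_duration_comparison(d2)
  expect_equal(as.character(attr(q2, "quartile"))[c(3, 5, 7)],
               c("Q1", "Q2", "Q3"))

  # permuting patient order permutes assignments identically
  perm <- sample(n)
  q3 <- quartile_duration_comparison(d[perm, ])
  expect_equal(as.character(attr(q3, "quartile")),
               as.character(asg[perm]))

  # tiny cohort with one outcome class in a quartile gets flagged
  d4 <- data.frame(ecvp_load = 1:8, ecvp_duration_hr = 1:8,
                   pct_ecvp_duration = 1:8,
                   death_28d = c(0, 0, 0, 0, 0, 0, 1, 1))
  q4 <- quartile_duration_comparison(d4)
  expect_true(any(q4$flag == "single_class"))
  expect_true(all(is.na(q4$p_value[q4$flag == "single_class"])))
})
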