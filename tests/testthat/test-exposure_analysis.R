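mk_dataset <- function(conc_by_rep, times, arm = "a", ab = "vancomycin") {
  # conc_by_rep: list of per-replicate concentration vectors over `times`
  do.call(rbind, lapply(seq_along(conc_by_rep), function(r) {
    data.frame(arm = arm, replicate = r, time_h = times, antibiotic = ab,
               conc_ug_ml = conc_by_rep[[r]], censored = 0L)
  }))
}

test_that("log summary computes geometric means with the LOD convention", {
  d <- mk_dataset(list(1, 100), times = 1)
  s <- summarize_log(d)
  expect_equal(s$log10_mean, 1) # geometric mean 10 ug/mL
  expect_equal(s$n, 2L)
  # fully censored group: recorded at the LOD, -0.01 log10 units at 2 dp
  dc <- mk_dataset(list(0.98, 0.98, 0.98), times = 2)
  dc$censored <- 1L
  sc <- summarize_log(dc)
  expect_equal(round(sc$log10_mean, 2), -0.01)
  expect_equal(sc$log10_se, 0)
  # single replicate: SE degenerate, reported as 0 with a flag
  d1 <- mk_dataset(list(5), times = 1)
  s1 <- summarize_log(d1)
  expect_equal(s1$log10_se, 0)
  expect_true(s1$se_degenerate)
  # exponentiating the log mean is the geometric mean computed directly
  vals <- c(3.2, 17, 81, 0.99)
  dg <- mk_dataset(as.list(vals), times = 1)
  expect_equal(10^summarize_log(dg)$log10_mean,
               prod(vals)^(1 / length(vals)))
})

test_that("trapezoidal AUC handles windows on the sampling grid", {
  times <- default_sampling_times()
  flat <- rep(10, length(times))
  # constant curve: rectangle from the first sample (5 min) to the window
  expect_equal(auc_trapezoid(times, flat, 2), 10 * (2 - 1 / 12))
  expect_equal(auc_trapezoid(times, flat, 48), 10 * (48 - 1 / 12))
  # window monotonicity for any non-negative series
  curve <- withr::with_seed(8, stats::runif(length(times), 0, 50))
  aucs <- vapply(c(2, 12, 24, 48), function(w)
    auc_trapezoid(times, curve, w), numeric(1))
  expect_true(all(diff(aucs) >= 0))
  # additivity over adjacent windows
  expect_equal(auc_trapezoid(times, curve, 12),
               auc_trapezoid(times, curve, 2) +
                 pracma::trapz(times[times >= 2 & times <= 12],
                               curve[times >= 2 & times <= 12]))
  expect_error(auc_trapezoid(times, flat, 96), "beyond")
  expect_error(auc_trapezoid(c(1, 1, 2), c(1, 1, 1), 2), "increasing")
})

test_that("sampled-grid AUC agrees with fine quadrature of the smooth arms", {
  fx <- noise_free_fixture(arms = c("spacer_only", "csb_plus_spacer"))
  for (arm in c("spacer_only", "csb_plus_spacer")) {
    sim <- sim_arm(arm)
    for (ab in c("vancomycin", "tobramycin")) {
      v <- fx[fx$arm == arm & fx$antibiotic == ab, ]
      v <- v[order(v$time_h), ]
      coarse <- auc_trapezoid(v$time_h, v$conc_ug_ml, 48)
      keep <- sim$series$time_h >= 1 / 12
      fine <- pracma::trapz(sim$series$time_h[keep],
                            sim$series$conc[keep, ab])
      expect_lt(abs(coarse - fine) / fine, 0.10)
    }
  }
})

test_that("per-replicate AUC windows cover every group", {
  fx <- noise_free_fixture(arms = c("spacer_only", "vp_bolus"))
  a <- auc_windows(fx)
  expect_named(a, c("arm", "replicate", "antibiotic", "window_h",
                    "auc_ug_h_ml"))
  # 2 arms x (2 + 1) antibiotic series x 4 windows, 1 replicate
  expect_equal(nrow(a), 12L)
  expect_true(all(a$auc_ug_h_ml >= 0))
  wide <- a[a$arm == "spacer_only" & a$antibiotic == "vancomycin", ]
  expect_true(all(diff(wide$auc_ug_h_ml[order(wide$window_h)]) >= 0))
})

test_that("log differences subtract arm summaries on matching grids", {
  times <- c(1, 2, 4)
  da <- mk_dataset(list(c(10, 20, 40), c(10, 20, 40)), times, arm = "a")
  db <- mk_dataset(list(c(10, 20, 40), c(10, 20, 40)), times, arm = "b")
  sa <- summarize_log(da); sb <- summarize_log(db)
  expect_equal(log_difference(sa, sa)$log10_diff, rep(0, 3))
  d100 <- mk_dataset(list(c(1000, 2000, 4000), c(1000, 2000, 4000)), times,
                     arm = "c")
  expect_equal(log_difference(summarize_log(d100), sb)$log10_diff,
               rep(2, 3))
  # invariance under common rescaling of both arms (no censoring involved)
  sa10 <- summarize_log(transform(da, conc_ug_ml = conc_ug_ml * 10))
  sb10 <- summarize_log(transform(db, conc_ug_ml = conc_ug_ml * 10))
  expect_equal(log_difference(sa10, sb10)$log10_diff,
               log_difference(sa, sb)$log10_diff)
  smis <- summarize_log(mk_dataset(list(c(1, 2)), c(1, 3), arm = "d"))
  expect_error(log_difference(sa, smis), "mismatch")
})

test_that("combined arm dominates the spacer alone in log difference", {
  fx <- noise_free_fixture(arms = c("spacer_only", "csb_plus_spacer"))
  s <- summarize_log(fx)
  ld <- log_difference(s[s$arm == "csb_plus_spacer", ],
                       s[s$arm == "spacer_only", ])
  expect_true(all(ld$log10_diff >= 0))
})

test_that("time above threshold integrates crossings by interpolation", {
  band <- threshold_band(low = 100, high = 750, duration_h = 24)
  times <- default_sampling_times()
  high <- rep(200, length(times))
  res <- time_above_threshold(times, high, band)
  expect_equal(res$hours_above, 48 - 1 / 12)
  expect_true(res$satisfied)
  low <- rep(50, length(times))
  res2 <- time_above_threshold(times, low, band)
  expect_equal(res2$hours_above, 0)
  expect_false(res2$satisfied)
  # bolus washout: time above equals the closed-form crossing time
  D <- 1000; V <- 75; Q <- 3.5
  sim <- simulate_reactor(single_depot_config(release_model("bolus", D),
                                              flow_ml_min = Q, volume = V,
                                              duration = 6))
  tstar <- V / (Q * 60) * log((D / V * 1000) / 100)
  res3 <- time_above_threshold(sim$series$time_h,
                               sim$series$conc[, "vancomycin"], band)
  expect_equal(res3$hours_above, tstar, tolerance = 1e-4)
  expect_false(res3$satisfied)
})

test_that("students_t reproduces the pooled-variance formula", {
  same <- c(1, 2, 3)
  res <- students_t(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand-computed oracle: n = 3 each, means 0 and 1, common sd 0.1
  a <- c(-0.1, 0, 0.1); b <- c(0.9, 1.0, 1.1)
  sp <- sqrt(((3 - 1) * stats::var(a) + (3 - 1) * stats::var(b)) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_manual <- 2 * stats::pt(abs(t_manual), df = 4, lower.tail = FALSE)
  res2 <- students_t(a, b)
  expect_equal(res2$statistic, t_manual, tolerance = 1e-10)
  expect_equal(res2$p_value, p_manual, tolerance = 1e-10)
  expect_equal(res2$df, 4)
  # swapping groups negates t and keeps p
  res3 <- students_t(b, a)
  expect_equal(res3$statistic, -res2$statistic)
  expect_equal(res3$p_value, res2$p_value)
  expect_error(students_t(c(1, 1), c(1, 1)), "degenerate")
  expect_error(students_t(1, c(1, 2)), "at least 2")
})

test_that("arm comparisons test every shared timepoint", {
  fx <- generate_arm_fixtures(arms = c("spacer_only", "csb_plus_spacer"),
                              n_replicates = 3, seed = 12)
  cmp <- compare_arms(fx, "csb_plus_spacer", "spacer_only")
  expect_equal(nrow(cmp), 2 * 23)
  expect_true(all(is.finite(cmp$p)))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_equal(attr(cmp, "adjust"), "none")
  cmph <- compare_arms(fx, "csb_plus_spacer", "spacer_only",
                       adjust = "holm")
  expect_true(all(cmph$p_adj >= cmph$p))
  expect_error(compare_arms(fx, "csb_plus_spacer", "vp_bolus"), "present")
})

test_that("exposure summary bundles the full analysis", {
  fx <- generate_arm_fixtures(n_replicates = 2, seed = 4)
  es <- exposure_summary(fx)
  expect_named(es, c("log_summary", "auc", "threshold", "log_diff",
                     "tests"))
  expect_true(all(c("csb_plus_spacer", "spacer_only", "vp_bolus") %in%
                    es$threshold$arm))
  # the bead-augmented arm sustains the band for 24 h; the bolus does not
  expect_true(all(es$threshold$satisfied[es$threshold$arm ==
                                           "csb_plus_spacer"]))
  expect_false(any(es$threshold$satisfied[es$threshold$arm == "vp_bolus"]))
})
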