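test_that("bolus washout matches the closed-form exponential", {
  D <- 1000; V <- 75; Q <- 3.5 # mL/min
  cfg <- single_depot_config(release_model("bolus", D), flow_ml_min = Q,
                             volume = V, duration = 6)
  sim <- simulate_reactor(cfg)
  t <- sim$series$time_h
  expected <- (D / V) * 1000 * exp(-Q * 60 * t / V)
  expect_equal(sim$series$conc[, "vancomycin"], expected,
               tolerance = 1e-6)
})

test_that("constant release under constant flow reaches k0/Q steady state", {
  k0 <- 12 # mg/h
  Q <- 3.5
  cfg <- single_depot_config(release_model("zero_order", 1e6, k0 = k0),
                             flow_ml_min = Q, duration = 48)
  sim <- simulate_reactor(cfg)
  n <- length(sim$series$time_h)
  steady <- k0 / (Q * 60) * 1000 # ug/mL
  expect_equal(unname(sim$series$conc[n, "vancomycin"]), steady,
               tolerance = 1e-6)
})

test_that("powder bolus starts at the load over the working volume", {
  sim <- sim_arm("vp_bolus")
  expect_equal(unname(sim$series$conc[1, "vancomycin"]), 1000 / 75 * 1000,
               tolerance = 1e-12)
  expect_equal(colnames(sim$series$conc), "vancomycin") # no tobramycin depot
})

test_that("washout half-time matches V ln2 / Q and scales with volume", {
  D <- 1000
  mk <- function(V) {
    simulate_reactor(single_depot_config(release_model("bolus", D),
                                         flow_ml_min = 3.5, volume = V,
                                         duration = 6))
  }
  expect_equal(washout_half_time(mk(75)), 75 * log(2) / 3.5,
               tolerance = 1e-4)
  expect_equal(washout_half_time(mk(150)) / washout_half_time(mk(75)), 2,
               tolerance = 1e-4)
  # under the clinical stepwise schedule the bolus halves in ~15 min
  expect_equal(round(washout_half_time(sim_arm("vp_bolus"))), 15)
  # never-halving signal
  slow <- simulate_reactor(single_depot_config(
    release_model("bolus", D), flow_ml_min = 0.001, volume = 75,
    duration = 1, solver_step_min = 1))
  expect_warning(ht <- washout_half_time(slow), "never")
  expect_true(is.na(ht))
})

test_that("mass audit closes the ledger and tightens under refinement", {
  for (arm in arm_names()) {
    sim <- sim_arm(arm)
    res <- mass_audit(sim)
    load <- sim$released_mg
    expect_true(all(abs(res) / load < 0.001))
  }
  coarse <- mass_audit(sim_arm("vp_bolus", solver_step_min = 1))
  fine <- mass_audit(sim_arm("vp_bolus", solver_step_min = 0.1))
  expect_lt(abs(fine), abs(coarse))
  # closed vessel: nothing washes out, everything stays in the reactor
  closed <- simulate_reactor(single_depot_config(
    release_model("bolus", 200), flow_ml_min = 0, volume = 75,
    duration = 2))
  expect_equal(unname(closed$washed_out_mg), 0)
  n <- length(closed$series$time_h)
  expect_equal(unname(closed$series$conc[n, "vancomycin"]) * 75 / 1000, 200)
  # no depots at all: empty ledgers
  empty_cfg <- reactor_config(list(), constant_schedule(1, 1))
  empty <- simulate_reactor(empty_cfg)
  expect_length(mass_audit(empty), 0)
})

test_that("concentration responds linearly to the loading", {
  alpha <- 3.7
  mk <- function(a) {
    depots <- list(
      list(spec = depot_spec("csb", c(vancomycin = 100 * a + 50 * a)),
           models = list(vancomycin = release_model("zero_order", 100 * a,
                                                    k0 = 10 * a))),
      list(spec = depot_spec("powder_bolus", c(vancomycin = 50 * a)),
           models = list(vancomycin = release_model("bolus", 50 * a))))
    simulate_reactor(reactor_config(depots, default_schedule(12),
                                    duration = 12))
  }
  s1 <- mk(1); s2 <- mk(alpha)
  expect_equal(s2$series$conc[, "vancomycin"],
               alpha * s1$series$conc[, "vancomycin"], tolerance = 1e-10)
})

test_that("release deconvolution inverts the forward simulation", {
  # zero-order law: estimated rate settles at k0 away from start-up
  k0 <- 1
  cfgz <- single_depot_config(release_model("zero_order", 1e6, k0 = k0),
                              flow_ml_min = 3.5, duration = 12)
  simz <- simulate_reactor(cfgz)
  rz <- deconvolve_release(simz$series, cfgz$schedule, volume = 75)
  interior <- rz$time_h >= 2 & rz$time_h <= 11.9
  expect_true(all(abs(rz$release_rate_mg_h[interior] - k0) / k0 < 0.05))
  # first-order law: round-trip within 5% relative on interior points
  fo <- release_model("first_order", 500, k1 = 0.15)
  cfgf <- single_depot_config(fo, flow_ml_min = 3.5, duration = 12)
  simf <- simulate_reactor(cfgf)
  rf <- deconvolve_release(simf$series, cfgf$schedule, volume = 75)
  interior <- rf$time_h >= 2 & rf$time_h <= 11.9
  truth <- release_rate(fo, rf$time_h[interior])
  expect_true(all(abs(rf$release_rate_mg_h[interior] - truth) / truth <
                    0.05))
  # bolus: no sustained release to recover
  cfgb <- single_depot_config(release_model("bolus", 1000),
                              flow_ml_min = 3.5, duration = 6)
  simb <- simulate_reactor(cfgb)
  expect_warning(
    rb <- deconvolve_release(simb$series, cfgb$schedule, volume = 75),
    "floored")
  expect_lt(max(rb$release_rate_mg_h[rb$time_h > 0.01]), 1)
  # duplicated times are rejected; irregular grids are fine
  bad <- concentration_series(c(1, 2, 3),
                              matrix(c(1, 2, 3), ncol = 1,
                                     dimnames = list(NULL, "vancomycin")))
  bad$time_h <- c(1, 1, 2)
  expect_error(deconvolve_release(bad, constant_schedule(1, 48)),
               "increasing")
  irr <- concentration_series(c(0.5, 1, 3, 7),
                              matrix(4:1, ncol = 1,
                                     dimnames = list(NULL, "vancomycin")))
  expect_silent(suppressWarnings(
    deconvolve_release(irr, constant_schedule(1, 48))))
})

test_that("simulation export writes the documented schema", {
  sim <- sim_arm("vp_bolus", solver_step_min = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(sim, f)
  df <- utils::read.csv(f)
  expect_named(df, c("time_h", "antibiotic", "conc_ug_ml", "flow_ml_min"))
  expect_equal(df$flow_ml_min[1], 3.5)
})
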