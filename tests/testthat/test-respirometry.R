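test_that("compute_mo2 matches the closed-chamber equation", {
  # hand arithmetic: (7.40 - 6.90) * (0.00165 / 0.25) / 0.050 = 0.066
  expect_equal(compute_mo2(7.40, 6.90, 0.00165, 0.25, 0.050), 0.066)
  expect_equal(compute_mo2(7.0, 7.0, 0.001, 1, 0.01), 0)
})

test_that("compute_mo2 proportionality properties hold on random inputs", {
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 6, 8); b <- runif(1, 3, 6)
    v <- runif(1, 1e-4, 2e-3); t <- runif(1, 0.1, 1); m <- runif(1, 0.01, 0.1)
    base <- compute_mo2(a, b, v, t, m)
    expect_equal(compute_mo2(a, b, v, t, 2 * m), base / 2)
    expect_equal(compute_mo2(a, b, 2 * v, t, m), 2 * base)
    expect_equal(compute_mo2(a, b, v, 2 * t, m), base / 2)
    expect_equal(compute_mo2(a + 1, b + 1, v, t, m), base)
  }
})

test_that("compute_mo2 validates domain and flags O2 production", {
  expect_error(compute_mo2(7, 6, 0, 1, 0.1), "volume")
  expect_error(compute_mo2(7, 6, 0.001, -1, 0.1), "elapsed")
  expect_error(compute_mo2(7, 6, 0.001, 1, 0), "mass")
  expect_warning(compute_mo2(6, 7, 0.001, 1, 0.1), "negative MO2")
})

test_that("q10 reproduces hand calculations and identities", {
  expect_equal(q10(1, 20, 2, 30), 2)
  expect_equal(q10(0.3, 12, 0.3, 25), 1)
  expect_equal(q10(0.05, 11, 0.15, 30), 3^(10 / 19))
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1); k <- runif(1, 0.5, 5)
    t1 <- runif(1, 5, 15); t2 <- runif(1, 20, 35); t3 <- runif(1, 36, 40)
    # scale invariance
    expect_equal(q10(k * a, t1, k * b, t2), q10(a, t1, b, t2))
    # composition along a common rate curve r(T)
    r <- function(temp) 0.05 * exp(0.08 * temp)
    lhs <- q10(r(t1), t1, r(t3), t3)^((t3 - t1) / 10)
    rhs <- q10(r(t1), t1, r(t2), t2)^((t2 - t1) / 10) *
      q10(r(t2), t2, r(t3), t3)^((t3 - t2) / 10)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  expect_error(q10(0, 10, 1, 20), "rates")
  expect_error(q10(1, 10, 1, 10), "differ")
})

test_that("blank_correct subtracts the mean blank slope", {
  expect_equal(blank_correct(-1.0, c(-0.1, -0.3))$slope, -0.8)
  expect_equal(blank_correct(-1.0, c(0, 0))$slope, -1.0)
  expect_warning(out <- blank_correct(-1.0, numeric(0)), "uncorrected")
  expect_equal(out$slope, -1.0)
  expect_equal(out$n_blanks, 0L)
  expect_error(blank_correct(-1, numeric(0), on_missing = "error"), "blank")
})

test_that("find_linear_window recovers an exactly linear slope", {
  tr <- make_trace(-0.8)
  w <- find_linear_window(tr)
  expect_equal(w$slope_per_h, -0.8, tolerance = 1e-9)
  expect_equal(w$r2, 1, tolerance = 1e-9)
  # window duration within the configured 5-10 min bounds
  expect_true(w$end_s - w$start_s >= 300 && w$end_s - w$start_s <= 600)
})

test_that("constant traces return slope 0 with r2 0 by convention", {
  tr <- oxygen_trace(seq(0, 1200, 15), rep(7, 81), 24, 0.00175)
  w <- find_linear_window(tr)
  expect_equal(w$slope_per_h, 0)
  expect_equal(w$r2, 0)
})

test_that("window selection skips a settling transient and matches the lm oracle", {
  set.seed(42)
  for (i in 1:5) {
    tr <- make_trace(runif(1, -2, -0.5), minutes = 20, noise_sd = 0.005,
                     transient_amp = 0.4, transient_tau = 120)
    w <- find_linear_window(tr)
    o <- brute_force_window(tr, engine = "lm")
    expect_equal(w$i0, o$i0)
    expect_equal(w$i1, o$i1)
    expect_equal(w$slope_per_h, o$slope_per_h, tolerance = 1e-8)
    # the 2-min transient start is excluded
    expect_gte(w$start_s, 120)
  }
})

test_that("min_residual_sd criterion agrees with its oracle", {
  set.seed(7)
  cfg <- window_config(criterion = "min_residual_sd")
  tr <- make_trace(-1.2, minutes = 15, noise_sd = 0.01, transient_amp = 0.3)
  w <- find_linear_window(tr, cfg)
  o <- brute_force_window(tr, cfg, engine = "lm")
  expect_equal(c(w$i0, w$i1), c(o$i0, o$i1))
})

test_that("short traces error, clamp, or fall back to the whole trace", {
  expect_error(find_linear_window(make_trace(-1, minutes = 3)),
               "shorter than the minimum")
  # barely above the minimum: whole trace with a warning
  expect_warning(w <- find_linear_window(make_trace(-1, minutes = 5.4)),
                 "whole trace")
  expect_equal(w$slope_per_h, -1, tolerance = 1e-9)
  # an 8-min TIMR-max style trace: admissible range clamped to length
  w8 <- find_linear_window(make_trace(-2, minutes = 8))
  expect_true(w8$end_s - w8$start_s <= 480)
  expect_equal(w8$slope_per_h, -2, tolerance = 1e-9)
})

test_that("oxygen_trace validates its invariants", {
  expect_error(oxygen_trace(c(0, 0, 1), c(7, 7, 7), 24, 1e-3), "increasing")
  expect_error(oxygen_trace(c(0, 1), c(7, -1), 24, 1e-3), ">= 0")
  expect_error(oxygen_trace(c(0, 1), c(7, 7), 24, 0), "volume")
  expect_error(oxygen_trace(0, 7, 24, 1e-3), "length")
})

test_that("process_run recovers noiseless rates exactly and books rejects", {
  cfg <- simulation_config(seed = 5, n_embryos_per_stage = 2,
                           stages = c(8, 12, 16, 19), noise_sd_o2 = 0)
  sim <- simulate_all(cfg)
  run <- process_run(sim$traces$traces, sim$cohort$cohort)
  truth <- sim$traces$truth
  m <- merge(run$rates, truth[!is.na(truth$embryo_id), ], by = "embryo_id")
  expect_equal(nrow(m), 8)
  expect_lt(max(abs(m$mo2_per_embryo - m$true_mo2_embryo) /
                  m$true_mo2_embryo), 1e-9)
  # invariant: specific rate is per-embryo rate over mass, exactly
  expect_identical(run$rates$mo2_specific,
                   run$rates$mo2_per_embryo / run$rates$mass_g)
  expect_equal(nrow(run$rejects), 0)

  # drop some embryos from the cohort: their vials land in the rejects
  cohort2 <- sim$cohort$cohort[-c(1, 2), ]
  run2 <- process_run(sim$traces$traces, cohort2)
  expect_equal(nrow(run2$rates), 6)
  expect_equal(nrow(run2$rejects), 2)
  expect_match(run2$rejects$reason, "not found", all = TRUE)
})

test_that("blank correction in process_run removes a known drift", {
  cfg <- simulation_config(seed = 6, n_embryos_per_stage = 1,
                           stages = c(10, 18), temperatures = 24,
                           noise_sd_o2 = 0, blank_drift = 0.4)
  sim <- simulate_all(cfg)
  run <- process_run(sim$traces$traces, sim$cohort$cohort)
  truth <- sim$traces$truth
  m <- merge(run$rates, truth[!is.na(truth$embryo_id), ], by = "embryo_id")
  expect_lt(max(abs(m$mo2_per_embryo - m$true_mo2_embryo) /
                  m$true_mo2_embryo), 1e-9)
  # without correction the drift contaminates the rate
  run_nc <- process_run(sim$traces$traces, sim$cohort$cohort,
                        blank_correction = FALSE)
  m_nc <- merge(run_nc$rates, truth[!is.na(truth$embryo_id), ],
                by = "embryo_id")
  expect_gt(max(abs(m_nc$mo2_per_embryo - m_nc$true_mo2_embryo) /
                  m_nc$true_mo2_embryo), 0.01)
})
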