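test_that("generation is deterministic in the seed and respects n", {
  cfg <- simulation_config(n = 500, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  c2 <- generate_cohort(simulation_config(n = 500, seed = 22))
  expect_false(identical(a$time_days, c2$time_days))
})

test_that("cohort tables carry the full analysis schema", {
  co <- generate_cohort(simulation_config(n = 80, seed = 5))
  expect_true(all(cohort_required_columns() %in% names(co)))
  expect_true(all(co$time_days > 0))
  expect_true(all(co$died_in_hospital %in% 0:1))
  expect_true(all(co$apache_ii >= 0))
  expect_true(all(as.matrix(co[, comorbidity_names()]) %in% 0:1))
  expect_identical(co$latent_accel, as.integer(co$latent_z > 0))
})

test_that("unattainable mortality targets fail the hazard tuning loudly", {
  cfg <- simulation_config(n = 100, seed = 1, target_mortality = 0.999,
                           discharge_median_days = 0.001,
                           discharge_sdlog = 0.1)
  expect_error(generate_cohort(cfg), "unattainable")
})

test_that("true_parameters echoes the configured effects and integrates to the target", {
  cfg <- simulation_config(n = 10000, seed = 33)
  tp <- true_parameters(cfg)
  expect_equal(tp$accel_log_hr, log(2))
  expect_equal(tp$target_mortality, 0.10)
  # quadrature over the discharge distribution vs the tuned conditional target
  expect_lt(abs(tp$expected_mortality - 0.10), 0.005)
  # zero-effect config: tuning fixed point still hits the target
  cfg0 <- simulation_config(n = 5000, seed = 34, accel_log_hr = 0,
                            apache_log_hr = 0)
  tp0 <- true_parameters(cfg0)
  expect_lt(abs(tp0$expected_mortality - 0.10), 0.005)
})

test_that("comorbid patients carry a higher latent aging factor where a shift is configured", {
  co <- generate_cohort(simulation_config(n = 20000, seed = 35))
  shifts <- phenoage:::default_z_shifts()
  for (cm in names(shifts)[shifts > 0]) {
    tt <- t.test(co$latent_z[co[[cm]] == 1], co$latent_z[co[[cm]] == 0])
    expect_gt(unname(tt$statistic), 0)
  }
})

test_that("hazard construction is recovered by a Cox fit on the latent indicator", {
  # averaged over three replicate cohorts so the check sits well inside the
  # sampling variability of a single n = 20000 draw
  hrs <- vapply(36:38, function(s) {
    co <- generate_cohort(simulation_config(n = 20000, seed = s,
                                            apache_log_hr = 0))
    cox_fit(co$time_days, co$died_in_hospital,
            as.matrix(co[, "latent_accel", drop = FALSE]))$coefficients$hr
  }, numeric(1))
  expect_gt(mean(hrs), 1.85)
  expect_lt(mean(hrs), 2.15)
})

test_that("accelerated-aging prevalence after recalibration brackets reality", {
  co <- add_phenoage_measures(generate_cohort(simulation_config(seed = 2)))
  prev <- mean(co$phenoage_accel)
  expect_gt(prev, 0.35)
  expect_lt(prev, 0.65)
  died <- mean(co$died_in_hospital)
  expect_gt(died, 0.05)
  expect_lt(died, 0.15)
})

test_that("dose-response simulator produces the requested hazard shape", {
  d <- simulate_residual_hazard(4000, beta = 0.05, shape = "linear",
                                seed = 3)
  expect_equal(nrow(d), 4000)
  expect_true(all(d$time_days > 0))
  # event probability rises with the residual under a positive slope
  hi <- mean(d$died[d$residual > 10]); lo <- mean(d$died[d$residual < -10])
  expect_gt(hi, lo)
})
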