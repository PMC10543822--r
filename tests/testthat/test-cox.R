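test_that("three-observation fixture recovers the closed-form partial-likelihood maximum", {
  f <- cox_fit(c(1, 2, 3), c(1, 1, 1),
               matrix(c(1, 0, 1), ncol = 1, dimnames = list(NULL, "x")))
  beta <- f$coefficients$coef
  expect_equal(beta, -0.5 * log(2), tolerance = 1e-6)
  expect_equal(beta, oracle_cox3_grid(), tolerance = 1e-5)
  expect_equal(f$coefficients$hr, 1 / sqrt(2), tolerance = 1e-6)
})

test_that("constant covariates are reported at hazard ratio 1 rather than failing", {
  f <- cox_fit(c(2, 4, 6, 8), c(1, 0, 1, 1),
               cbind(flat = rep(3, 4), x = c(1, 0, 0, 1)))
  flat <- f$coefficients[f$coefficients$term == "flat", ]
  expect_equal(flat$coef, 0)
  expect_equal(flat$hr, 1)
  expect_true(is.na(flat$se))
  expect_true(is.finite(f$coefficients$coef[2]))
})

test_that("partial likelihood is invariant to duplicating every row", {
  set.seed(61)
  n <- 150
  x <- cbind(z = rbinom(n, 1, 0.4))
  tt <- rexp(n, exp(-2 + 0.6 * x[, 1]))
  ev <- rbinom(n, 1, 0.8)
  ev[1] <- 1
  # exact under Breslow; Efron redistributes the duplication-induced ties,
  # so it agrees only approximately
  f1 <- cox_fit(tt, ev, x, ties = "breslow")
  f2 <- cox_fit(rep(tt, 2), rep(ev, 2), rbind(x, x), ties = "breslow")
  expect_equal(f2$coefficients$coef, f1$coefficients$coef,
               tolerance = 1e-6)
  e1 <- cox_fit(tt, ev, x)
  e2 <- cox_fit(rep(tt, 2), rep(ev, 2), rbind(x, x))
  expect_equal(e2$coefficients$coef, e1$coefficients$coef,
               tolerance = 0.01)
})

test_that("degenerate inputs are rejected with clear messages", {
  expect_error(cox_fit(c(1, 2), c(0, 0), cbind(x = c(1, 0))), "no events")
  expect_error(cox_fit(c(1, -2), c(1, 0), cbind(x = c(1, 0))), "positive")
  expect_error(cox_fit(c(1, 2), c(1, 2), cbind(x = c(1, 0))), "binary")
  expect_error(cox_fit(c(1, 2), c(1, 0), cbind(x = c(NA, 0))), "missing")
})

test_that("hazard ratios, intervals and concordance are internally consistent", {
  co <- generate_cohort(simulation_config(n = 2000, seed = 62))
  f <- cox_fit(co$time_days, co$died_in_hospital,
               as.matrix(co[, c("latent_accel", "apache_ii")]))
  cf <- f$coefficients
  expect_equal(cf$hr, exp(cf$coef))
  expect_true(all(cf$ci_low <= cf$hr & cf$hr <= cf$ci_high))
  expect_gt(f$concordance, 0.5)
  # the true risk score discriminates better than pure noise on every seed
  for (s in 1:5) {
    set.seed(62 + s)
    noise <- rnorm(nrow(co))
    f_true <- cox_fit(co$time_days, co$died_in_hospital,
                      cbind(risk = attr(co, "truth")$accel_log_hr *
                              co$latent_accel + 0.07 * co$apache_ii))
    f_noise <- cox_fit(co$time_days, co$died_in_hospital,
                       cbind(noise = noise))
    expect_gt(f_true$concordance, f_noise$concordance)
  }
})

test_that("an empty adjuster list reduces the ladder to the univariable fit", {
  co <- generate_cohort(simulation_config(n = 800, seed = 63))
  co$phenoage_accel <- co$latent_accel
  lad <- sequential_cox(co, "phenoage_accel", character())
  expect_equal(nrow(lad$ladder), 1)
  uni <- cox_fit(co$time_days, co$died_in_hospital,
                 as.matrix(co[, "phenoage_accel", drop = FALSE]))
  expect_equal(lad$ladder$hr, uni$coefficients$hr)
})

test_that("the ladder has one row per adjuster in configured order", {
  co <- add_phenoage_measures(generate_cohort(
    simulation_config(n = 1500, seed = 64)))
  co$apache_gt15 <- as.integer(co$apache_ii > 15)
  adj <- c("age_years", "elective_surgery", "diabetes")
  lad <- sequential_cox(co, "phenoage_accel", adj,
                        final_extra = "apache_gt15")
  expect_equal(nrow(lad$ladder), length(adj) + 1)
  expect_equal(lad$ladder$model[2], "phenoage_accel + age_years")
  expect_equal(lad$final$term,
               c("phenoage_accel", adj, "apache_gt15"))
})

test_that("an adjuster independent of exposure and outcome barely moves the focal hazard ratio", {
  co <- generate_cohort(simulation_config(n = 20000, seed = 65,
                                          apache_log_hr = 0))
  co$phenoage_accel <- co$latent_accel
  set.seed(66)
  co$irrelevant <- rbinom(nrow(co), 1, 0.5)
  lad <- sequential_cox(co, "phenoage_accel", "irrelevant")
  expect_lt(abs(lad$ladder$hr[2] - lad$ladder$hr[1]), 0.02)
})

test_that("significance-gated entry drops uninformative adjusters", {
  co <- generate_cohort(simulation_config(n = 5000, seed = 67))
  co$phenoage_accel <- co$latent_accel
  set.seed(68)
  co$irrelevant <- rbinom(nrow(co), 1, 0.5)
  lad <- sequential_cox(co, "phenoage_accel",
                        c("apache_ii", "irrelevant"), p_entry = 0.05)
  expect_true("phenoage_accel + apache_ii" %in% lad$ladder$model)
  expect_false(any(grepl("irrelevant", lad$ladder$model)))
})
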