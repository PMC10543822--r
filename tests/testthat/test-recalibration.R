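test_that("age gap is the signed difference in years", {
  expect_equal(age_gap(91.5, 63), 28.5)
  expect_equal(age_gap(63, 63), 0)
  expect_equal(age_gap(50, 70), -20)
  expect_error(age_gap(Inf, 60), "finite")
})

test_that("an exact linear relation yields zero residuals and no accelerated patients", {
  ages <- c(40, 50, 55, 63, 71, 80)
  fit <- fit_age_regression(33.4 + 1.2 * ages, ages)
  expect_equal(fit$slope, 1.2, tolerance = 1e-10)
  expect_equal(fit$intercept, 33.4, tolerance = 1e-10)
  expect_equal(fit$residual, rep(0, 6), tolerance = 1e-10)
  # residual exactly 0 is not accelerated (strict inequality)
  expect_false(any(fit$accel_flag))
})

test_that("five-point fit matches the closed-form normal equations", {
  ages <- c(50, 60, 70, 40, 65)
  pheno <- c(80, 95, 120, 60, 100)
  # hand oracle: Sxx = 580, Sxy = 1065 about the means (57, 91)
  fit <- fit_age_regression(pheno, ages)
  expect_equal(fit$slope, 1065 / 580, tolerance = 1e-10)
  expect_equal(fit$intercept, 91 - 57 * 1065 / 580, tolerance = 1e-10)
  expect_equal(sign(fit$residual), c(1, -1, 1, 1, -1))
  flags <- classify_phenoage_accel(fit)
  expect_equal(as.logical(flags), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(sum(flags), 3)
  expect_equal(attr(flags, "intercept"), fit$intercept)

  # reflecting every point about the fitted line flips every flag
  reflected <- 2 * fit$fitted - pheno
  fit2 <- fit_age_regression(reflected, ages)
  expect_equal(fit2$accel_flag, !fit$accel_flag)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_age_regression(c(70, 80), c(60, 60)), "degenerate")
  expect_error(fit_age_regression(c(70, 80, 90), c(60, 65)), "length")
  expect_error(fit_age_regression(70, 60), "at least 2")
})

test_that("residuals satisfy the least-squares orthogonality identities", {
  set.seed(31)
  ages <- runif(300, 20, 90)
  pheno <- 30 + 1.1 * ages + rnorm(300, 0, 12)
  fit <- fit_age_regression(pheno, ages)
  expect_lt(abs(sum(fit$residual)), 1e-8 * fit$n)
  expect_lt(abs(sum(fit$residual * ages)), 1e-6 * fit$n)
  # adding a constant shifts the intercept only: no residual, hence no flag,
  # changes
  fit_c <- fit_age_regression(pheno + 7.5, ages)
  expect_equal(fit_c$intercept, fit$intercept + 7.5, tolerance = 1e-8)
  expect_equal(fit_c$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit_c$residual, fit$residual, tolerance = 1e-8)
  expect_identical(fit_c$accel_flag, fit$accel_flag)
})

test_that("symmetric zero-mean noise flags about half the cohort at n = 3000", {
  set.seed(32)
  ages <- runif(3000, 20, 90)
  pheno <- 25 + 1.2 * ages + rnorm(3000, 0, 15)
  fit <- fit_age_regression(pheno, ages)
  frac <- mean(fit$accel_flag)
  # binomial(3000, 0.5) +- 4 sd
  expect_gt(frac, 0.5 - 4 * sqrt(0.25 / 3000))
  expect_lt(frac, 0.5 + 4 * sqrt(0.25 / 3000))
})

test_that("add_phenoage_measures augments the cohort CSV schema consistently", {
  co <- generate_cohort(simulation_config(n = 120, seed = 13))
  aug <- add_phenoage_measures(co)
  expect_true(all(c("phenoage_years", "age_gap_years",
                    "accel_residual_years", "phenoage_accel") %in%
                    names(aug)))
  expect_equal(aug$age_gap_years, aug$phenoage_years - aug$age_years)
  expect_identical(aug$phenoage_accel,
                   as.integer(aug$accel_residual_years > 0))
})
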