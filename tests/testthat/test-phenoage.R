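test_that("panel validation clamps CRP and rejects out-of-range analytes", {
  p <- reference_panel()
  expect_identical(validate_panel(p), p)

  p0 <- p; p0$crp <- 0
  expect_equal(validate_panel(p0)$crp, 0.01)

  phigh <- p; phigh$lymphocyte_pct <- 150
  expect_error(validate_panel(phigh), "lymphocyte_pct")

  pneg <- p; pneg$albumin <- -3
  expect_error(validate_panel(pneg), "albumin")
  pna <- p; pna$wbc <- NaN
  expect_error(validate_panel(pna), "wbc")
})

test_that("unit dialect conversion rescales CRP, glucose and accepts both WBC codes", {
  p <- reference_panel()
  p_mgl <- p; p_mgl$crp <- p$crp * 10
  expect_equal(convert_panel_units(p_mgl, crp_unit = "mg_l"), p)
  p_mgdl <- p; p_mgdl$glucose <- p$glucose * 18.016
  expect_equal(convert_panel_units(p_mgdl, glucose_unit = "mg_dl"), p)
  expect_equal(convert_panel_units(p, wbc_unit = "10e3_ul"), p)
})

test_that("linear predictor is linear in age and coefficients and hits the golden value", {
  cf <- phenoage_coefficients()
  p <- reference_panel()
  xb60 <- linear_predictor(p, 60, cf)
  expect_equal(linear_predictor(p, 61, cf) - xb60, cf$age, tolerance = 1e-12)
  # golden fixture: independent evaluation of the published transform
  expect_equal(xb60, oracle_phenoage(p, 60)$xb, tolerance = 1e-12)
  expect_equal(xb60, -8.040967, tolerance = 1e-6)
  # doubling a weight doubles that term's contribution
  cf2 <- cf; cf2$rdw <- 2 * cf$rdw
  expect_equal(linear_predictor(p, 60, cf2) - xb60, cf$rdw * p$rdw,
               tolerance = 1e-10)
})

test_that("mortality score is monotone in xb and clamped at extremes", {
  cf <- phenoage_coefficients()
  grid <- seq(-30, 10, length.out = 1000)
  m <- mortality_risk(grid, cf)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m > 0 & m < 1))
  expect_equal(mortality_risk(-700, cf), 1e-12)
  expect_equal(mortality_risk(700, cf), 1 - 1e-12)
  expect_equal(mortality_risk(-8.040967, cf), 0.0615294,
               tolerance = 1e-5)
})

test_that("risk inversion recovers the age scale and round-trips", {
  cf <- phenoage_coefficients()
  # inner product 1 => phenoage equals the offset constant exactly; the
  # default inv_a puts that risk too close to 1 for double precision, so the
  # identity is exercised with a representable inversion constant
  cf_id <- cf
  cf_id$inv_a <- -0.5
  m_unit <- 1 - exp(1 / cf_id$inv_a)
  expect_equal(phenoage_from_risk(m_unit, cf_id), cf_id$inv_c,
               tolerance = 1e-10)
  expect_error(phenoage_from_risk(0, cf), "strictly")
  expect_error(phenoage_from_risk(1.2, cf), "strictly")
  m <- seq(0.001, 0.999, length.out = 200)
  expect_equal(risk_from_phenoage(phenoage_from_risk(m, cf), cf), m,
               tolerance = 1e-9)
})

test_that("compute_phenoage matches the independent oracle on the reference panel and 50 random panels", {
  p <- reference_panel()
  got <- compute_phenoage(p, 60)
  ora <- oracle_phenoage(p, 60)
  expect_equal(got$xb, ora$xb, tolerance = 1e-9)
  expect_equal(got$mortality_risk, ora$m, tolerance = 1e-9)
  expect_equal(got$phenoage, ora$phenoage, tolerance = 1e-9)
  expect_equal(got$phenoage, 54.713133, tolerance = 1e-5)
  # interior risks: the stable composition agrees with the probability path
  expect_equal(got$phenoage, phenoage_from_risk(got$mortality_risk),
               tolerance = 1e-9)

  set.seed(401)
  panels <- random_panels(50)
  ages <- runif(50, 18, 95)
  got <- compute_phenoage(panels, ages)
  ora <- oracle_phenoage(panels, ages)
  expect_equal(got$phenoage, ora$phenoage, tolerance = 1e-9)
})

test_that("phenoage moves in the direction of each biomarker's weight", {
  cf <- phenoage_coefficients()
  set.seed(402)
  panels <- random_panels(100)
  ages <- runif(100, 20, 90)
  base <- compute_phenoage(panels, ages, cf)$phenoage
  weights <- c(albumin = cf$albumin, creatinine = cf$creatinine,
               glucose = cf$glucose, crp = cf$log_crp,
               lymphocyte_pct = cf$lymphocyte_pct, mcv = cf$mcv,
               rdw = cf$rdw, alp = cf$alp, wbc = cf$wbc)
  for (a in names(weights)) {
    bumped <- panels
    bumped[[a]] <- bumped[[a]] * 1.001
    shifted <- compute_phenoage(bumped, ages, cf)$phenoage
    expect_true(all(sign(shifted - base) == sign(weights[[a]])),
                info = paste("direction of", a))
  }
  # identical inputs give identical results
  expect_identical(compute_phenoage(panels, ages, cf),
                   compute_phenoage(panels, ages, cf))
})

test_that("coefficients are injectable from a file and defaults load reproducibly", {
  cf <- phenoage_coefficients()
  alt_file <- tempfile(fileext = ".json")
  alt <- unclass(cf)[c("intercept", "albumin", "creatinine", "glucose",
                       "log_crp", "lymphocyte_pct", "mcv", "rdw", "alp",
                       "wbc", "age", "gompertz_gamma", "horizon_months",
                       "inv_a", "inv_b", "inv_c")]
  alt$age <- alt$age + 0.01
  alt$name <- "bumped_age_weight"
  jsonlite::write_json(alt, alt_file, auto_unbox = TRUE, digits = NA)
  cf2 <- phenoage_coefficients(alt_file)
  p <- reference_panel()
  expect_equal(linear_predictor(p, 60, cf2) - linear_predictor(p, 60, cf),
               0.01 * 60, tolerance = 1e-9)
  # defaults bit-identical across loads, checksum recorded
  cf3 <- phenoage_coefficients()
  expect_identical(unclass(cf)[names(unclass(cf))],
                   unclass(cf3)[names(unclass(cf3))])
  expect_match(attr(cf, "checksum"), "^[0-9a-f]{32}$")
  # broken file is rejected
  bad <- alt; bad$gompertz_gamma <- -1
  jsonlite::write_json(bad, alt_file, auto_unbox = TRUE)
  expect_error(phenoage_coefficients(alt_file), "gompertz_gamma")
})

test_that("score_cohort appends phenoage from the CSV column dialect", {
  co <- generate_cohort(simulation_config(n = 50, seed = 9))
  scored <- score_cohort(co)
  expect_true("phenoage_years" %in% names(scored))
  p <- biomarker_panel(co$albumin_g_l, co$creatinine_umol_l,
                       co$glucose_mmol_l, co$crp_mg_dl, co$lymphocyte_pct,
                       co$mcv_fl, co$rdw_pct, co$alp_u_l, co$wbc_10e9_l)
  expect_equal(scored$phenoage_years,
               compute_phenoage(p, co$age_years)$phenoage)
})
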