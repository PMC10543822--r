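# Synthetic ICU cohort generator. The point is validation: every downstream
# stage (scoring, recalibration, discrimination, Cox ladders, splines) can be
# exercised against a cohort whose hazard structure is known exactly.
#
# Design: a latent aging factor z (standard normal, shifted upward by
# comorbidity-specific increments) drives both the biomarker panel and the
# death hazard. Acceleration enters survival through 1{z > 0}, NOT through
# the computed regression residual, so the PhenoAgeAccel flag measured
# downstream is a noisy readout of the truth -- which is what makes
# attenuation and recovery experiments meaningful.

#' Names of the comorbidity flags carried by a cohort table
#' @return Character vector of the eleven chronic-condition flag columns.
#' @export
comorbidity_names <- function() {
  c("chronic_respiratory", "chronic_cardiovascular", "esrf", "cirrhosis",
    "immune_disease", "immunosuppressed", "lymphoma", "leukemia",
    "metastatic_cancer", "aids", "diabetes")
}

default_prevalences <- function() {
  c(chronic_respiratory = 0.041, chronic_cardiovascular = 0.077,
    esrf = 0.043, cirrhosis = 0.022, immune_disease = 0.022,
    immunosuppressed = 0.080, lymphoma = 0.019, leukemia = 0.018,
    metastatic_cancer = 0.055, aids = 0.002, diabetes = 0.232)
}

# upward shift of the latent aging factor per comorbidity; sized so the
# comorbidity/acceleration odds ratios are clearly positive where the
# condition plausibly accelerates aging (renal failure strongest)
default_z_shifts <- function() {
  c(chronic_respiratory = 0.2, chronic_cardiovascular = 0.5,
    esrf = 2.0, cirrhosis = 0.8, immune_disease = 0.5,
    immunosuppressed = 0.5, lymphoma = 0.2, leukemia = 0.2,
    metastatic_cancer = 0.0, aids = 0.0, diabetes = 0.9)
}

# additive mean shifts (canonical units) of each biomarker per comorbidity;
# clinically motivated entries only, everything else zero
default_biomarker_shifts <- function() {
  m <- matrix(0, nrow = length(comorbidity_names()), ncol = 9,
              dimnames = list(comorbidity_names(), biomarker_names()))
  m["diabetes", "glucose"] <- 3
  m["cirrhosis", "albumin"] <- -6
  m["cirrhosis", "alp"] <- 60
  m["esrf", "creatinine"] <- 350
  m["metastatic_cancer", "alp"] <- 40
  m["leukemia", "wbc"] <- 5
  m["lymphoma", "wbc"] <- 2
  m
}

#' Configuration for the synthetic ICU cohort generator
#'
#' Defaults emulate a mixed medical-surgical tertiary ICU cohort: about 2950
#' patients, median age in the low 60s, roughly 10\% hospital mortality,
#' chronic-condition prevalences of a few percent (diabetes 23\%), and a
#' latent acceleration factor that doubles the death hazard.
#'
#' @param n Number of patients.
#' @param seed Integer root seed; every random stream derives from it.
#' @param age_mean,age_sd,age_bounds Truncated-normal age distribution
#'   (years).
#' @param comorbidity_prevalences Named probabilities for the flags of
#'   \code{\link{comorbidity_names}}.
#' @param elective_prevalence Probability of elective surgical admission.
#' @param comorbidity_z_shifts Named upward shifts of the latent aging factor
#'   per comorbidity.
#' @param biomarker_shift_matrix Comorbidity-by-biomarker matrix of additive
#'   mean shifts in canonical units.
#' @param accel_log_hr Log hazard ratio for the latent acceleration indicator
#'   \code{1\{z > 0\}}. Default \code{log(2)}.
#' @param apache_log_hr Log hazard ratio per APACHE II point (centred at 15).
#' @param target_mortality Expected hospital mortality the baseline hazard is
#'   tuned to. Default 0.10.
#' @param discharge_median_days,discharge_sdlog Log-normal competing
#'   discharge-time distribution (survivors' stay), days.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n = 2950, seed = 1L,
                              age_mean = 60, age_sd = 16,
                              age_bounds = c(18, 95),
                              comorbidity_prevalences = default_prevalences(),
                              elective_prevalence = 0.274,
                              comorbidity_z_shifts = default_z_shifts(),
                              biomarker_shift_matrix = default_biomarker_shifts(),
                              accel_log_hr = log(2),
                              apache_log_hr = 0.07,
                              target_mortality = 0.10,
                              discharge_median_days = 10,
                              discharge_sdlog = 0.9) {
  stopifnot(n >= 1, is.finite(seed),
            age_bounds[1] < age_bounds[2], age_sd > 0,
            all(comorbidity_prevalences >= 0 & comorbidity_prevalences <= 1),
            elective_prevalence >= 0, elective_prevalence <= 1,
            target_mortality > 0, target_mortality < 1,
            discharge_median_days > 0, discharge_sdlog > 0)
  missing <- setdiff(comorbidity_names(), names(comorbidity_prevalences))
  if (length(missing) > 0) {
    stop("comorbidity_prevalences missing: ", paste(missing, collapse = ", "))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 age_bounds = age_bounds,
                 comorbidity_prevalences = comorbidity_prevalences,
                 elective_prevalence = elective_prevalence,
                 comorbidity_z_shifts = comorbidity_z_shifts,
                 biomarker_shift_matrix = biomarker_shift_matrix,
                 accel_log_hr = accel_log_hr,
                 apache_log_hr = apache_log_hr,
                 target_mortality = target_mortality,
                 discharge_median_days = discharge_median_days,
                 discharge_sdlog = discharge_sdlog),
            class = "simulation_config")
}

# one root seed -> a fixed table of per-block substream seeds, so adding a
# later block never perturbs earlier draws
block_seeds <- function(seed, k = 8) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# covariates, discharge times and the tuned baseline hazard (no death draws)
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  bs <- block_seeds(config$seed)

  set.seed(bs[1])                                   # block 1: ages
  age <- round(rtruncnorm(n, config$age_mean, config$age_sd,
                          config$age_bounds[1], config$age_bounds[2]))

  set.seed(bs[2])                                   # block 2: flags
  flags <- vapply(comorbidity_names(), function(cm) {
    stats::rbinom(n, 1L, config$comorbidity_prevalences[[cm]])
  }, integer(n))
  if (n == 1) flags <- matrix(flags, nrow = 1,
                              dimnames = list(NULL, comorbidity_names()))
  elective <- stats::rbinom(n, 1L, config$elective_prevalence)

  set.seed(bs[3])                                   # block 3: latent factor
  zshift <- drop(flags %*% config$comorbidity_z_shifts[comorbidity_names()])
  z <- stats::rnorm(n) + zshift

  set.seed(bs[4])                                   # block 4: biomarkers
  shifts <- flags %*% config$biomarker_shift_matrix[comorbidity_names(), ]
  a60 <- age - 60
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  panel <- data.frame(
    albumin = clamp(42 - 0.06 * a60 - 1.5 * z + shifts[, "albumin"] +
                      rnorm(n, 0, 4), 10, 60),
    creatinine = clamp(80 + 0.4 * a60 + 12 * z + shifts[, "creatinine"] +
                         rnorm(n, 0, 20), 20, 1500),
    glucose = clamp(6 + 0.4 * z + shifts[, "glucose"] + rnorm(n, 0, 1.5),
                    2.5, 30),
    crp = clamp(exp(rnorm(n, log(3) + 0.5 * z, 1)) + shifts[, "crp"],
                0, 60),
    lymphocyte_pct = clamp(15 - 2.5 * z + shifts[, "lymphocyte_pct"] +
                             rnorm(n, 0, 6), 0.5, 60),
    mcv = clamp(90 + 1.5 * z + 0.05 * a60 + shifts[, "mcv"] + rnorm(n, 0, 5),
                60, 130),
    rdw = clamp(14 + 0.8 * z + shifts[, "rdw"] + rnorm(n, 0, 1.5), 10, 30),
    alp = clamp(85 + 12 * z + shifts[, "alp"] + rnorm(n, 0, 35), 10, 1500),
    wbc = clamp(11 + 1.5 * z + shifts[, "wbc"] + rnorm(n, 0, 4), 0.3, 80))

  set.seed(bs[5])                                   # block 5: severity
  apache <- pmax(0L, as.integer(round(14 + 0.08 * a60 + 2.5 * z +
                                        rnorm(n, 0, 6))))

  set.seed(bs[6])                                   # block 6: discharge
  discharge <- stats::rlnorm(n, log(config$discharge_median_days),
                             config$discharge_sdlog)

  # relative hazard and baseline tuning: E[mortality | covariates, discharge]
  # = mean(1 - exp(-lambda * C)) must equal the target
  rel <- exp(config$accel_log_hr * (z > 0) +
               config$apache_log_hr * (apache - 15))
  f <- function(b0) mean(1 - exp(-exp(b0) * rel * discharge)) -
    config$target_mortality
  lo <- -25; hi <- 5
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target_mortality unattainable: baseline hazard tuning failed to ",
         "bracket the target")
  }
  b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root

  list(age = age, flags = flags, elective = elective, z = z, panel = panel,
       apache = apache, discharge = discharge, rel_hazard = rel,
       baseline_log_hazard = b0, seeds = bs)
}

#' Generate a synthetic ICU cohort with known hazard structure
#'
#' Draws ages, comorbidity flags, a latent aging factor, biomarkers, APACHE II
#' severity, competing discharge times and death times as described in the
#' package vignette. Death times are exponential with
#' log-hazard \code{baseline + accel_log_hr * 1\{z > 0\} + apache_log_hr *
#' (APACHE - 15)}; the baseline is tuned by root-finding so the expected
#' hospital mortality equals \code{target_mortality}. Survivors are censored
#' at discharge; recorded follow-up is in whole days (ceiling), so ties are
#' common, as in real hospital data.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{data.frame} (class \code{cohort_table}) with identifiers,
#'   \code{age_years}, the nine panel columns in CSV dialect, comorbidity
#'   flags, \code{elective_surgery}, \code{apache_ii},
#'   \code{died_in_hospital}, \code{time_days}, and the simulation-only
#'   ground-truth columns \code{latent_z} and \code{latent_accel}. Ground
#'   truth parameters are attached as attribute \code{truth}.
#' @examples
#' cohort <- generate_cohort(simulation_config(n = 200, seed = 7))
#' mean(cohort$died_in_hospital)
#' @export
generate_cohort <- function(config = simulation_config()) {
  cov <- simulate_covariates(config)
  n <- config$n
  set.seed(cov$seeds[7])                            # block 7: death draws
  lambda <- exp(cov$baseline_log_hazard) * cov$rel_hazard
  t_death <- stats::rexp(n, rate = 1) / lambda
  died <- t_death <= cov$discharge
  time <- pmax(1, ceiling(pmin(t_death, cov$discharge)))

  cols <- panel_columns()
  panel <- cov$panel
  names(panel) <- unname(cols[names(panel)])

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    hosp_id = sprintf("H%05d", seq_len(n)),
    admission_order = 1L,
    age_years = cov$age,
    panel,
    as.data.frame(cov$flags),
    elective_surgery = cov$elective,
    apache_ii = cov$apache,
    died_in_hospital = as.integer(died),
    time_days = as.numeric(time),
    latent_z = cov$z,
    latent_accel = as.integer(cov$z > 0))
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "truth") <- list(
    seed = config$seed, n = n,
    accel_log_hr = config$accel_log_hr,
    apache_log_hr = config$apache_log_hr,
    baseline_log_hazard = cov$baseline_log_hazard,
    target_mortality = config$target_mortality)
  cohort
}

#' Ground-truth parameters of a simulation configuration
#'
#' Reconstructs the tuned baseline hazard for a configuration and recomputes
#' the expected hospital mortality by numerical integration of the competing
#' death/discharge model over the log-normal discharge distribution
#' (midpoint quadrature on discharge quantiles), independently of the
#' discharge times actually drawn.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param n_quad Number of quadrature nodes.
#' @return List with \code{accel_log_hr}, \code{apache_log_hr},
#'   \code{baseline_log_hazard}, \code{target_mortality} and
#'   \code{expected_mortality}.
#' @export
true_parameters <- function(config = simulation_config(), n_quad = 512) {
  cov <- simulate_covariates(config)
  lambda <- exp(cov$baseline_log_hazard) * cov$rel_hazard
  q <- stats::qlnorm((seq_len(n_quad) - 0.5) / n_quad,
                     log(config$discharge_median_days),
                     config$discharge_sdlog)
  surv_given_c <- vapply(q, function(cc) mean(exp(-lambda * cc)), numeric(1))
  list(accel_log_hr = config$accel_log_hr,
       apache_log_hr = config$apache_log_hr,
       baseline_log_hazard = cov$baseline_log_hazard,
       target_mortality = config$target_mortality,
       expected_mortality = 1 - mean(surv_given_c))
}

#' Simulate survival data with a known residual dose-response shape
#'
#' Companion simulator for validating the spline dose-response stage: draws an
#' age-acceleration residual \code{x ~ N(0, sd)} and exponential survival
#' times whose log-hazard is either exactly linear in \code{x} or linear with
#' a plateau beyond a threshold, with uniform administrative censoring.
#'
#' @param n Number of patients.
#' @param beta Log hazard ratio per year of residual.
#' @param shape \code{"linear"} or \code{"plateau"}.
#' @param plateau_at Residual (years) beyond which the hazard stops rising
#'   (plateau shape only).
#' @param resid_sd Standard deviation of the residual distribution, years.
#' @param censor_max Upper bound of the uniform censoring time, days.
#' @param seed Integer seed.
#' @return data.frame with \code{residual}, \code{time_days}, \code{died}.
#' @export
simulate_residual_hazard <- function(n, beta = 0.03,
                                     shape = c("linear", "plateau"),
                                     plateau_at = 20, resid_sd = 15,
                                     censor_max = 60, seed = 1L) {
  shape <- match.arg(shape)
  set.seed(seed)
  x <- rnorm(n, 0, resid_sd)
  g <- if (shape == "linear") x else pmin(x, plateau_at)
  lambda <- exp(-3.5 + beta * g)
  t_death <- stats::rexp(n, rate = 1) / lambda
  cens <- runif(n, 0, censor_max)
  data.frame(residual = x,
             time_days = pmin(t_death, cens),
             died = as.integer(t_death <= cens))
}
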