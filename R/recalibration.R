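# Cohort recalibration: phenotypic age is regressed on chronological age
# within the study cohort, so that "accelerated aging" means being
# biologically older than expected relative to peers in the same setting
# rather than relative to an external reference population.

#' Signed gap between phenotypic and chronological age
#'
#' @param phenoage Phenotypic age, years.
#' @param age Chronological age, years.
#' @return \code{phenoage - age}, in years. The signed convention is used so
#'   the direction of divergence is preserved; take \code{abs()} for a
#'   magnitude.
#' @export
age_gap <- function(phenoage, age) {
  if (any(!is.finite(phenoage)) || any(!is.finite(age))) {
    stop("phenoage and age must be finite")
  }
  phenoage - age
}

#' Regress phenotypic age on chronological age within a cohort
#'
#' Ordinary least squares of phenotypic age (response) on chronological age
#' (single predictor) over the whole cohort. The residual is each patient's
#' age acceleration relative to cohort expectation; a strictly positive
#' residual defines the acceleration flag. The fitted intercept is the
#' cohort's recalibration constant: the phenotypic-age excess over
#' chronological age at which acceleration begins (at slope 1).
#'
#' @param phenoages Phenotypic ages, years.
#' @param ages Chronological ages, years; same length, at least two distinct
#'   values.
#' @return An object of class \code{recalibration_fit}: list with
#'   \code{slope}, \code{intercept} (years), \code{fitted}, \code{residual}
#'   (years, one per patient), \code{accel_flag} (logical, residual > 0) and
#'   \code{n}.
#' @examples
#' fit <- fit_age_regression(c(80, 95, 120, 60, 100), c(50, 60, 70, 40, 65))
#' fit$slope
#' sum(fit$accel_flag)
#' @export
fit_age_regression <- function(phenoages, ages) {
  if (length(phenoages) != length(ages)) {
    stop("phenoages and ages must have equal length")
  }
  n <- length(ages)
  if (n < 2) stop("need at least 2 patients")
  if (any(!is.finite(phenoages)) || any(!is.finite(ages))) {
    stop("phenoages and ages must be finite")
  }
  if (length(unique(ages)) < 2) {
    stop("degenerate design: all chronological ages are equal")
  }
  fit <- stats::lm(phenoages ~ ages)
  cf <- stats::coef(fit)
  res <- unname(stats::residuals(fit))
  # residuals within numerical noise of an exact fit count as zero, so a
  # patient lying exactly on the cohort line is never flagged; the tolerance
  # (~1e-8 years at cohort scale) is far below clinical resolution
  tol <- 1e-8 * max(1, stats::sd(phenoages))
  structure(list(slope = unname(cf[2]),
                 intercept = unname(cf[1]),
                 fitted = unname(stats::fitted(fit)),
                 residual = res,
                 accel_flag = res > tol,
                 n = n),
            class = "recalibration_fit")
}

#' Extract acceleration flags from a recalibration fit
#'
#' @param fit A \code{\link{fit_age_regression}} result.
#' @return Logical vector of per-patient flags (residual strictly positive;
#'   a residual of exactly zero is not accelerated). The cohort's
#'   recalibration constant (the regression intercept, in years) is attached
#'   as attribute \code{intercept}.
#' @export
classify_phenoage_accel <- function(fit) {
  stopifnot(inherits(fit, "recalibration_fit"))
  structure(fit$accel_flag, intercept = fit$intercept)
}

#' @export
print.recalibration_fit <- function(x, ...) {
  cat("Cohort recalibration of phenotypic age on chronological age\n")
  cat(sprintf("  n = %d patients\n", x$n))
  cat(sprintf("  PhenoAge = %.3f + %.4f * age  (years)\n",
              x$intercept, x$slope))
  cat(sprintf("  accelerated (residual > 0): %d (%.1f%%)\n",
              sum(x$accel_flag), 100 * mean(x$accel_flag)))
  invisible(x)
}

#' Append phenotypic-age measures to a cohort table
#'
#' Scores the cohort, fits the within-cohort age regression, and appends the
#' three derived measures: \code{phenoage_years}, the signed
#' \code{age_gap_years}, the recalibrated \code{accel_residual_years}, and
#' the dichotomous \code{phenoage_accel} flag (0/1).
#'
#' @param cohort Cohort table with panel columns and \code{age_years}.
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @param crp_floor CRP clamp floor, mg/dL.
#' @return The augmented cohort; the \code{recalibration_fit} is attached as
#'   attribute \code{recalibration}.
#' @export
add_phenoage_measures <- function(cohort, coeffs = phenoage_coefficients(),
                                  crp_floor = 0.01) {
  cohort <- score_cohort(cohort, coeffs, crp_floor = crp_floor)
  fit <- fit_age_regression(cohort$phenoage_years, cohort$age_years)
  cohort$age_gap_years <- age_gap(cohort$phenoage_years, cohort$age_years)
  cohort$accel_residual_years <- fit$residual
  cohort$phenoage_accel <- as.integer(fit$accel_flag)
  attr(cohort, "recalibration") <- fit
  cohort
}
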