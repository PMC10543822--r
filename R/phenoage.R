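# Core phenotypic-age transform: weighted linear predictor over the nine
# biomarkers and chronological age -> Gompertz mortality score over a fixed
# horizon -> inversion back onto an age scale in years.

#' Linear predictor of the phenotypic-age model
#'
#' Computes \eqn{xb = b_0 + \sum_i w_i t_i + w_{age} \cdot age}, where the
#' CRP term is \code{log(crp)} and every other term is the raw canonical-unit
#' value.
#'
#' @param panel Validated biomarker panel (see \code{\link{validate_panel}}).
#' @param age Chronological age in years (recycled against panel rows).
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @return Numeric vector of linear-predictor values (dimensionless).
#' @export
linear_predictor <- function(panel, age, coeffs = phenoage_coefficients()) {
  stopifnot(inherits(coeffs, "phenoage_coefficients"))
  if (any(!is.finite(age))) stop("age must be finite")
  if (any(panel$crp <= 0)) {
    stop("crp must be positive after clamping; run validate_panel() first")
  }
  coeffs$intercept +
    coeffs$albumin        * panel$albumin +
    coeffs$creatinine     * panel$creatinine +
    coeffs$glucose        * panel$glucose +
    coeffs$log_crp        * log(panel$crp) +
    coeffs$lymphocyte_pct * panel$lymphocyte_pct +
    coeffs$mcv            * panel$mcv +
    coeffs$rdw            * panel$rdw +
    coeffs$alp            * panel$alp +
    coeffs$wbc            * panel$wbc +
    coeffs$age            * age
}

#' Gompertz mortality score from the linear predictor
#'
#' Maps the linear predictor through the Gompertz cumulative hazard over the
#' model horizon (120 months by default):
#' \eqn{M = 1 - \exp(-e^{xb}(e^{\gamma h} - 1)/\gamma)}. The result is clamped
#' into \code{[eps, 1 - eps]} so downstream logs stay finite for arbitrarily
#' extreme input.
#'
#' @param xb Linear predictor values.
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @param eps Clamping margin at both ends. Default 1e-12.
#' @return Mortality probabilities over the horizon, strictly inside (0, 1).
#' @export
mortality_risk <- function(xb, coeffs = phenoage_coefficients(), eps = 1e-12) {
  stopifnot(inherits(coeffs, "phenoage_coefficients"))
  if (any(!is.finite(xb))) stop("xb must be finite")
  g <- coeffs$gompertz_gamma
  cumhaz <- exp(xb) * (exp(g * coeffs$horizon_months) - 1) / g
  m <- 1 - exp(-cumhaz)
  pmin(pmax(m, eps), 1 - eps)
}

#' Invert a mortality score onto the age scale
#'
#' \eqn{PhenoAge = c + \log(a \cdot \log(1 - M)) / b} with \eqn{a < 0}, so the
#' inner product is positive for any \eqn{M} in (0, 1).
#'
#' @param m Mortality probabilities, strictly in (0, 1).
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @return Phenotypic age in years.
#' @export
phenoage_from_risk <- function(m, coeffs = phenoage_coefficients()) {
  stopifnot(inherits(coeffs, "phenoage_coefficients"))
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= 1)) {
    stop("mortality risk must lie strictly in (0, 1)")
  }
  coeffs$inv_c + log(coeffs$inv_a * log(1 - m)) / coeffs$inv_b
}

#' Compute phenotypic age from a biomarker panel and chronological age
#'
#' Composition of \code{\link{validate_panel}}, \code{\link{linear_predictor}},
#' \code{\link{mortality_risk}} and \code{\link{phenoage_from_risk}}.
#'
#' @param panel Biomarker panel data.frame in canonical units.
#' @param age Chronological age in years.
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @param crp_floor CRP clamp floor in mg/dL, passed to
#'   \code{\link{validate_panel}}.
#' @return A data.frame with columns \code{xb} (linear predictor),
#'   \code{mortality_risk} (horizon mortality probability) and
#'   \code{phenoage} (years), one row per patient.
#' @examples
#' p <- biomarker_panel(albumin = 40, creatinine = 80, glucose = 5, crp = 0.1,
#'                      lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70,
#'                      wbc = 7)
#' compute_phenoage(p, age = 60)
#' @export
compute_phenoage <- function(panel, age, coeffs = phenoage_coefficients(),
                             crp_floor = 0.01) {
  panel <- validate_panel(panel, crp_floor = crp_floor)
  xb <- linear_predictor(panel, age, coeffs)
  m <- mortality_risk(xb, coeffs)
  # exact composition: log(1 - M) is minus the Gompertz cumulative hazard,
  # so the age transform is evaluated in log space. This is algebraically
  # identical to phenoage_from_risk(mortality_risk(xb)) but does not lose
  # precision when M approaches 1 (severely deranged panels), where the
  # probability path would cap phenotypic age near 121 years.
  g <- coeffs$gompertz_gamma
  log_cumhaz <- xb + log((exp(g * coeffs$horizon_months) - 1) / g)
  phenoage <- coeffs$inv_c + (log(-coeffs$inv_a) + log_cumhaz) / coeffs$inv_b
  data.frame(xb = xb, mortality_risk = m, phenoage = phenoage)
}

#' Score a cohort table with phenotypic age
#'
#' Reads the nine panel columns (CSV dialect, e.g. \code{albumin_g_l}) and
#' \code{age_years} from a cohort table and appends a \code{phenoage_years}
#' column.
#'
#' @param cohort Cohort data.frame with the panel columns and
#'   \code{age_years}.
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @param crp_floor CRP clamp floor, mg/dL.
#' @return The cohort with \code{phenoage_years} appended.
#' @export
score_cohort <- function(cohort, coeffs = phenoage_coefficients(),
                         crp_floor = 0.01) {
  if (!"age_years" %in% names(cohort)) stop("cohort is missing age_years")
  panel <- panel_from_cohort(cohort)
  res <- compute_phenoage(panel, cohort$age_years, coeffs,
                          crp_floor = crp_floor)
  cohort$phenoage_years <- res$phenoage
  cohort
}
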