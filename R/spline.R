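# Restricted cubic splines (Harrell parameterization) and the spline
# dose-response curve of hospital-mortality hazard against the
# age-acceleration residual.

#' Restricted cubic spline basis (4 knots)
#'
#' Harrell's truncated-power parameterization: for knots
#' \eqn{t_1 < t_2 < t_3 < t_4} the basis holds the linear term plus two
#' nonlinear terms
#' \deqn{C_j(x) = [(x - t_j)_+^3 - (x - t_3)_+^3 (t_4 - t_j)/(t_4 - t_3)
#'   + (x - t_4)_+^3 (t_3 - t_j)/(t_4 - t_3)] / (t_4 - t_1)^2, j = 1, 2,}
#' which is linear beyond both boundary knots and continuous (with continuous
#' first and second derivatives) everywhere.
#'
#' @param x Numeric values (years of residual, here).
#' @param knots Strictly ascending vector of 4 knot locations.
#' @return Matrix with columns \code{linear}, \code{nl1}, \code{nl2}.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 4) stop("exactly 4 knots required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly ascending")
  tau <- (knots[4] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  nl <- function(tj) {
    (cube(x - tj) -
       cube(x - knots[3]) * (knots[4] - tj) / (knots[4] - knots[3]) +
       cube(x - knots[4]) * (knots[3] - tj) / (knots[4] - knots[3])) / tau
  }
  cbind(linear = x, nl1 = nl(knots[1]), nl2 = nl(knots[2]))
}

#' Default knot placement for a 4-knot spline
#'
#' Quantiles 5/35/65/95 of the observed distribution, the standard placement
#' for 4 knots.
#'
#' @param x Numeric values.
#' @return Numeric vector of 4 knots.
#' @export
rcs_knots <- function(x) {
  k <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95)))
  if (any(diff(k) <= 0)) stop("degenerate knot placement: tied quantiles")
  k
}

#' Spline dose-response curve of mortality hazard on the residual
#'
#' Fits a Cox model on the 3-column restricted cubic spline basis of the
#' age-acceleration residual and returns the log hazard ratio curve relative
#' to residual \code{ref} (default 0, the cohort expectation), with
#' delta-method pointwise confidence bands, plus a 2-df Wald test of the
#' nonlinear terms.
#'
#' @param time Follow-up time, days.
#' @param event Binary event indicator.
#' @param residual Age-acceleration residual per patient, years.
#' @param knots Knot locations; default \code{\link{rcs_knots}} of the
#'   residuals.
#' @param ref Reference residual at which the curve is 0.
#' @param grid Evaluation grid; default 101 points over the observed range.
#' @param conf_level Confidence level for the bands.
#' @return Object of class \code{spline_curve}: \code{knots}, \code{curve}
#'   (data.frame \code{x, loghr, ci_low, ci_high}), \code{p_nonlinear}
#'   (Wald test that both nonlinear coefficients are 0), \code{fit}.
#' @export
spline_hazard_curve <- function(time, event, residual, knots = NULL,
                                ref = 0, grid = NULL, conf_level = 0.95) {
  if (any(!is.finite(residual))) stop("residual must be finite")
  if (is.null(knots)) knots <- rcs_knots(residual)
  basis <- rcs_basis(residual, knots)
  fit <- cox_fit(time, event, basis)
  beta <- fit$coefficients$coef
  V <- vcov(fit$fit)
  if (is.null(grid)) {
    grid <- seq(min(residual), max(residual), length.out = 101)
  }
  contrast <- rcs_basis(grid, knots) -
    matrix(rcs_basis(ref, knots), nrow = length(grid), ncol = 3,
           byrow = TRUE)
  loghr <- drop(contrast %*% beta)
  se <- sqrt(rowSums((contrast %*% V) * contrast))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  curve <- data.frame(x = grid, loghr = loghr,
                      ci_low = loghr - zq * se, ci_high = loghr + zq * se)
  nl <- 2:3
  w <- drop(t(beta[nl]) %*% solve(V[nl, nl]) %*% beta[nl])
  structure(list(knots = knots, curve = curve,
                 p_nonlinear = pchisq(w, df = 2, lower.tail = FALSE),
                 coefficients = fit$coefficients, fit = fit),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat("Restricted cubic spline hazard curve\n")
  cat("  knots (years):", paste(round(x$knots, 2), collapse = ", "), "\n")
  rng <- range(x$curve$x)
  cat(sprintf("  log HR range over [%.1f, %.1f]: [%.3f, %.3f]\n",
              rng[1], rng[2], min(x$curve$loghr), max(x$curve$loghr)))
  cat(sprintf("  Wald test of nonlinearity (2 df): p = %.3g\n",
              x$p_nonlinear))
  invisible(x)
}
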