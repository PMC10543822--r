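# Hanley-McNeil sample-size calculation for detecting an AUROC above 0.5.

#' Hanley-McNeil variance of an AUC estimate
#'
#' \eqn{V = [\theta(1-\theta) + (n_{pos}-1)(Q_1-\theta^2) +
#' (n_{neg}-1)(Q_2-\theta^2)] / (n_{pos} n_{neg})} with
#' \eqn{Q_1 = \theta/(2-\theta)} and \eqn{Q_2 = 2\theta^2/(1+\theta)}.
#'
#' @param theta True AUC.
#' @param n_pos,n_neg Numbers of positives (events) and negatives.
#' @return Variance of the empirical AUC.
#' @export
hanley_mcneil_var <- function(theta, n_pos, n_neg) {
  q1 <- theta / (2 - theta)
  q2 <- 2 * theta^2 / (1 + theta)
  (theta * (1 - theta) + (n_pos - 1) * (q1 - theta^2) +
      (n_neg - 1) * (q2 - theta^2)) / (n_pos * n_neg)
}

#' Sample size to detect an AUROC above chance (Hanley-McNeil)
#'
#' Finds the smallest number of positives (events) such that, with
#' \code{neg_pos_ratio} negatives per positive, the one-sided normal
#' criterion
#' \eqn{z_{1-\alpha/2}\sqrt{V_0} + z_{power}\sqrt{V_1} \le \theta - \theta_0}
#' holds, where \eqn{V_0} and \eqn{V_1} are the Hanley-McNeil variances under
#' the null (\eqn{\theta_0}, default 0.5) and alternative AUC. Alpha is
#' spent two-sided, as in significance testing of the fitted curve.
#'
#' @param theta Target AUC, strictly above \code{theta0}.
#' @param alpha Two-sided significance level. Default 0.05.
#' @param power Desired power. Default 0.80.
#' @param neg_pos_ratio Negatives per positive (e.g. 10 for ~9\% event
#'   prevalence). Default 10.
#' @param theta0 Null AUC. Default 0.5.
#' @param n_max Search cap on the number of positives.
#' @return List with \code{n_pos}, \code{n_neg}
#'   (\code{round(neg_pos_ratio * n_pos)}) and \code{n_total}.
#' @examples
#' auroc_sample_size(0.60)$n_total  # 814
#' auroc_sample_size(0.65)$n_total  # 363
#' @export
auroc_sample_size <- function(theta, alpha = 0.05, power = 0.80,
                              neg_pos_ratio = 10, theta0 = 0.5,
                              n_max = 1e6) {
  if (!is.finite(theta) || theta <= theta0 || theta >= 1) {
    stop("theta must lie strictly between theta0 and 1")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (neg_pos_ratio <= 0) stop("neg_pos_ratio must be positive")
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  delta <- theta - theta0
  for (n_pos in 2:n_max) {
    n_neg <- round(neg_pos_ratio * n_pos)
    if (n_neg < 2) next
    v0 <- hanley_mcneil_var(theta0, n_pos, n_neg)
    v1 <- hanley_mcneil_var(theta, n_pos, n_neg)
    if (za * sqrt(v0) + zb * sqrt(v1) <= delta) {
      return(list(n_pos = n_pos, n_neg = n_neg, n_total = n_pos + n_neg))
    }
  }
  stop("no sample size up to n_max satisfies the criterion")
}
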