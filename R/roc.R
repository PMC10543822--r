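# ROC discrimination. The AUC is the Mann-Whitney concordance probability
# (ties count one half); variances come from DeLong's placement-value theory,
# computed with midranks so large cohorts never need an O(n^2) pairwise pass.

# placement values: v_pos[i] = P-hat(score of a random negative < pos_i),
# v_neg[j] = P-hat(score of pos > neg_j); mean of either is the AUC
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v_pos <- (r_all[seq_len(n1)] - r_pos) / n0
  v_neg <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(auc = mean(v_pos), v_pos = v_pos, v_neg = v_neg, n_pos = n1,
       n_neg = n0)
}

check_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both outcome classes must be present")
  }
  labels
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney AUC (tied score pairs count one half) with the DeLong
#' placement-value variance and a Wald 95\% confidence interval.
#'
#' @param scores Numeric predictor values (higher = more likely positive).
#' @param labels Binary outcome (0/1 or logical), same length.
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return Object of class \code{roc_result}: list with \code{auc},
#'   \code{ci_low}, \code{ci_high}, \code{se}, \code{n_pos}, \code{n_neg}.
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
auroc <- function(scores, labels, conf_level = 0.95) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pl <- delong_placements(scores, labels)
  # a class with a single member contributes no estimable between-subject
  # variance; its component is zero and the interval collapses accordingly
  var0 <- function(x) if (length(x) < 2) 0 else stats::var(x)
  v <- var0(pl$v_pos) / pl$n_pos + var0(pl$v_neg) / pl$n_neg
  se <- sqrt(v)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = pl$auc,
                 ci_low = max(0, pl$auc - zq * se),
                 ci_high = min(1, pl$auc + zq * se),
                 se = se, n_pos = pl$n_pos, n_neg = pl$n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f), %d events / %d non-events\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test comparing two correlated ROC curves
#'
#' Both scores must be measured on the same patients (paired design). The
#' test statistic uses the joint placement-value covariance of the two
#' markers; two-sided p-value from the normal reference.
#'
#' @param scores_a,scores_b Paired predictor values.
#' @param labels Binary outcome shared by both.
#' @return List with \code{auc_a}, \code{auc_b}, \code{difference}
#'   (\code{auc_a - auc_b}), \code{se}, \code{z}, \code{p_value}.
#' @export
compare_auroc <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("scores and labels must have equal length (paired design)")
  }
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("paired curve comparison needs at least two subjects per class")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  d <- pa$auc - pb$auc
  v <- (stats::var(pa$v_pos) + stats::var(pb$v_pos) -
          2 * stats::cov(pa$v_pos, pb$v_pos)) / pa$n_pos +
       (stats::var(pa$v_neg) + stats::var(pb$v_neg) -
          2 * stats::cov(pa$v_neg, pb$v_neg)) / pa$n_neg
  if (v <= 0 || !is.finite(v)) {
    # identical (or perfectly coupled) curves: no evidence of a difference
    return(list(auc_a = pa$auc, auc_b = pb$auc, difference = d, se = 0,
                z = 0, p_value = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d, se = sqrt(v), z = z,
       p_value = 2 * pnorm(-abs(z)))
}
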