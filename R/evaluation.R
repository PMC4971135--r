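# Detector evaluation: DET curves, EER, AUC, cost-optimal operating point,
# Wald confidence intervals and confusion-matrix statistics.

norm_deviate <- function(p) stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6))

#' DET curve points
#'
#' Sweeps the decision threshold over the pooled sorted unique scores (plus
#' -Inf/+Inf sentinels) with the convention "accept when score >= threshold":
#' the false-alarm rate is the fraction of non-target scores at or above the
#' threshold and the miss (false-rejection) rate the fraction of target
#' scores below it. Normal-deviate coordinates are clipped to
#' `[1e-6, 1 - 1e-6]` so perfect separation stays finite.
#'
#' @param target_scores,nontarget_scores numeric score vectors (both
#'   nonempty).
#' @return data frame with `threshold`, `far`, `frr`, `far_nd`, `frr_nd`,
#'   ordered by increasing threshold (FAR decreasing, FRR increasing).
#' @export
det_points <- function(target_scores, nontarget_scores) {
  if (length(target_scores) == 0L || length(nontarget_scores) == 0L)
    stop("both score lists must be nonempty")
  th <- c(-Inf, sort(unique(c(target_scores, nontarget_scores))), Inf)
  far <- vapply(th, function(t) mean(nontarget_scores >= t), numeric(1L))
  frr <- vapply(th, function(t) mean(target_scores < t), numeric(1L))
  data.frame(threshold = th, far = far, frr = frr,
             far_nd = norm_deviate(far), frr_nd = norm_deviate(frr))
}

#' Equal error rate
#'
#' The operating point where the false-alarm and false-rejection rates are
#' equal. When no threshold attains it exactly, the rate is linearly
#' interpolated between the two adjacent DET points straddling the
#' `FAR = FRR` diagonal.
#'
#' @inheritParams det_points
#' @return scalar EER as a fraction in `[0, 1]`.
#' @export
eer <- function(target_scores, nontarget_scores) {
  d <- det_points(target_scores, nontarget_scores)
  g <- d$far - d$frr                  # decreasing from 1 to -1
  i <- which(g <= 0)[1L]
  if (g[i] == 0) return(d$far[i])
  # interpolate between point i-1 (g > 0) and i (g < 0)
  t <- g[i - 1L] / (g[i - 1L] - g[i])
  d$frr[i - 1L] + t * (d$frr[i] - d$frr[i - 1L])
}

#' Area under the ROC curve
#'
#' Computed as the Mann--Whitney statistic `P(target > nontarget) +
#' 0.5 * P(tie)` via ranks, which equals trapezoidal integration of the
#' empirical ROC.
#'
#' @inheritParams det_points
#' @return scalar AUC in `[0, 1]`; 1 for an ideal detector.
#' @export
roc_auc <- function(target_scores, nontarget_scores) {
  nt <- length(target_scores); nn <- length(nontarget_scores)
  if (nt == 0L || nn == 0L) stop("both score lists must be nonempty")
  r <- rank(c(target_scores, nontarget_scores))
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nn)
}

#' Cost slope of the optimal ROC operating point
#'
#' `S = (C_FP - C_TN) / (C_FN - C_TP) * P(+D) / P(-D)`. With the default
#' costs (false decisions cost 0.5, correct ones 0) and equal priors, S = 1.
#'
#' @param costs named vector/list with `cfp`, `ctn`, `cfn`, `ctp`.
#' @param priors length-2 vector `c(P(+D), P(-D))`, summing to 1.
#' @return scalar slope S.
#' @export
cost_slope <- function(costs = c(cfp = 0.5, ctn = 0, cfn = 0.5, ctp = 0),
                       priors = c(0.5, 0.5)) {
  costs <- as.list(costs)
  if (costs$cfn == costs$ctp) stop("degenerate costs: C_FN must differ from C_TP")
  (costs$cfp - costs$ctn) / (costs$cfn - costs$ctp) * priors[1L] / priors[2L]
}

#' Cost-optimal operating point
#'
#' Selects the threshold minimizing the expected decision cost
#' `P(+D) * C_FN * FRR + P(-D) * C_FP * FAR + const` — the point at which the
#' ROC slope equals `S` of [cost_slope()]. The empirical ROC is a step
#' function, so the point is located by direct cost minimization (ties broken
#' toward the smaller threshold), which is exact where slope matching on the
#' steps is not.
#'
#' @inheritParams det_points
#' @inheritParams cost_slope
#' @return list with `threshold`, `far`, `frr`, `slope` (S), `cost`.
#' @export
optimal_operating_point <- function(target_scores, nontarget_scores,
                                    costs = c(cfp = 0.5, ctn = 0, cfn = 0.5,
                                              ctp = 0),
                                    priors = c(0.5, 0.5)) {
  S <- cost_slope(costs, priors)
  cl <- as.list(costs)
  d <- det_points(target_scores, nontarget_scores)
  cost <- priors[1L] * (cl$cfn * d$frr + cl$ctp * (1 - d$frr)) +
    priors[2L] * (cl$cfp * d$far + cl$ctn * (1 - d$far))
  i <- which.min(cost)
  list(threshold = d$threshold[i], far = d$far[i], frr = d$frr[i],
       slope = S, cost = cost[i])
}

#' Wald confidence interval for a cross-validated error rate
#'
#' Treats the classifier error as binomial: `p_cv -/+ z_{alpha/2} *
#' sqrt(p_cv * (1 - p_cv) / n)`, clipped to `[0, 1]`.
#'
#' @param p_cv mean error over folds, in `[0, 1]`.
#' @param n number of samples.
#' @param alpha 1 - confidence level (default 0.2 for an 80% interval).
#' @return length-2 vector `c(lo, hi)`.
#' @export
wald_ci <- function(p_cv, n, alpha = 0.2) {
  stopifnot(p_cv >= 0, p_cv <= 1, n >= 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  s <- sqrt(p_cv * (1 - p_cv) / n)
  c(lo = max(0, p_cv - z * s), hi = min(1, p_cv + z * s))
}

#' Confusion-matrix statistics for a binary task
#'
#' Positive polarity follows the detector's hypothesis class (e.g. healthy in
#' the healthy-infant detector): sensitivity is the fraction of positives
#' correctly identified, specificity the fraction of negatives, and
#' `FNR = 1 - sensitivity`, `FPR = 1 - specificity`.
#'
#' @param predictions,labels equal-length logical/0-1 vectors (TRUE/1 =
#'   positive).
#' @return list with `accuracy`, `sensitivity`, `specificity`, `fpr`, `fnr`
#'   (rates are `NA` when the corresponding class is absent from `labels`).
#' @export
confusion_stats <- function(predictions, labels) {
  predictions <- as.logical(predictions); labels <- as.logical(labels)
  if (length(predictions) != length(labels)) stop("length mismatch")
  np <- sum(labels); nn <- sum(!labels)
  sens <- if (np > 0L) sum(predictions & labels) / np else NA_real_
  spec <- if (nn > 0L) sum(!predictions & !labels) / nn else NA_real_
  list(accuracy = mean(predictions == labels),
       sensitivity = sens, specificity = spec,
       fpr = 1 - spec, fnr = 1 - sens)
}
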