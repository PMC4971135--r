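test_that("DET points match an exhaustive counting oracle", {
  set.seed(71)
  ts <- stats::rnorm(150, 1)
  ns <- stats::rnorm(200, -1)
  d <- det_points(ts, ns)
  # oracle: brute-force counting at every threshold
  for (i in seq_len(nrow(d))) {
    th <- d$threshold[i]
    expect_identical(d$far[i], mean(ns >= th))
    expect_identical(d$frr[i], mean(ts < th))
  }
  # sentinels: -Inf accepts everything, +Inf rejects everything
  expect_equal(d$far[1L], 1); expect_equal(d$frr[1L], 0)
  expect_equal(d$far[nrow(d)], 0); expect_equal(d$frr[nrow(d)], 1)
  expect_true(all(diff(d$far) <= 0))
  expect_true(all(diff(d$frr) >= 0))
  expect_true(all(is.finite(d$far_nd)))
  expect_error(det_points(numeric(0), ns), "nonempty")
})

test_that("EER is 0 for perfect separation, ~0.5 for chance, Phi(-1) for unit-gap Gaussians", {
  expect_equal(eer(c(3, 4, 5), c(0, 1, 2)), 0)
  expect_equal(eer(c(0, 1, 2), c(3, 4, 5)), 1)
  set.seed(72)
  same <- stats::rnorm(5000)
  expect_lt(abs(eer(same, stats::rnorm(5000)) - 0.5), 0.03)
  # d' = 2: theoretical EER = Phi(-1) ~ 0.1587
  ts <- stats::rnorm(20000, 1); ns <- stats::rnorm(20000, -1)
  expect_lt(abs(eer(ts, ns) - stats::pnorm(-1)), 0.01)
  # symmetric exact case: one target below, one nontarget above -> 0.5
  expect_equal(eer(c(0, 2), c(1, -1)), 0.5)
})

test_that("AUC equals the Mann-Whitney probability and handles ties", {
  set.seed(73)
  ts <- stats::rnorm(80, 0.8)
  ns <- stats::rnorm(120)
  # brute-force pairwise oracle
  want <- mean(outer(ts, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(ts, ns), want, tolerance = 1e-12)
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(roc_auc(c(0, 1), c(2, 3)), 0)
  expect_equal(roc_auc(c(1, 1), c(1, 1)), 0.5)
  # swapping roles mirrors around 0.5
  expect_equal(roc_auc(ts, ns) + roc_auc(ns, ts), 1, tolerance = 1e-12)
  # invariance to monotone transforms
  expect_equal(roc_auc(exp(ts), exp(ns)), roc_auc(ts, ns), tolerance = 1e-12)
})

test_that("EER is invariant to monotone score transforms", {
  set.seed(74)
  ts <- stats::rnorm(500, 1); ns <- stats::rnorm(500, -1)
  expect_equal(eer(2 * ts + 5, 2 * ns + 5), eer(ts, ns), tolerance = 1e-12)
  expect_equal(eer(exp(ts), exp(ns)), eer(ts, ns), tolerance = 1e-12)
})

test_that("cost slope follows the defining ratio", {
  expect_equal(cost_slope(), 1)
  expect_equal(cost_slope(priors = c(0.25, 0.75)), 1 / 3)
  expect_equal(cost_slope(c(cfp = 1, ctn = 0, cfn = 0.5, ctp = 0)), 2)
  expect_error(cost_slope(c(cfp = 1, ctn = 0, cfn = 0.2, ctp = 0.2)),
               "degenerate")
})

test_that("the cost-optimal operating point minimizes the expected cost", {
  set.seed(75)
  ts <- stats::rnorm(2000, 1); ns <- stats::rnorm(2000, -1)
  op <- optimal_operating_point(ts, ns)
  expect_equal(op$slope, 1)
  # exhaustive check: no threshold gives lower cost
  d <- det_points(ts, ns)
  costs <- 0.5 * 0.5 * d$frr + 0.5 * 0.5 * d$far
  expect_equal(op$cost, min(costs), tolerance = 1e-12)
  # symmetric Gaussians with S = 1: optimum is near the EER point (the
  # empirical cost surface is flat near the bottom, so allow a few percent)
  expect_lt(abs(op$far - eer(ts, ns)), 0.05)
  expect_lt(abs(op$frr - eer(ts, ns)), 0.05)
  # skewed false-alarm cost pushes the threshold up (fewer false alarms)
  op2 <- optimal_operating_point(ts, ns,
                                 costs = c(cfp = 2, ctn = 0, cfn = 0.1,
                                           ctp = 0))
  expect_lt(op2$far, op$far)
})

test_that("Wald interval matches hand-computed cases", {
  expect_equal(wald_ci(0, 100), c(lo = 0, hi = 0))
  expect_equal(wald_ci(1, 50), c(lo = 1, hi = 1))
  # p = 0.5, n = 100, 80%: half-width = 1.281552 * 0.05
  ci <- wald_ci(0.5, 100)
  expect_equal(unname(ci[2] - ci[1]), 2 * stats::qnorm(0.9) * 0.05,
               tolerance = 1e-9)
  # p = 0.2, n = 65, 95%
  ci2 <- wald_ci(0.2, 65, alpha = 0.05)
  hw <- stats::qnorm(0.975) * sqrt(0.2 * 0.8 / 65)
  expect_equal(unname(ci2), c(0.2 - hw, 0.2 + hw), tolerance = 1e-9)
  expect_error(wald_ci(1.2, 10), "p_cv")
})

test_that("confusion statistics match the 2x2 table", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cs <- confusion_stats(pred, lab)
  expect_equal(cs$accuracy, 4 / 6)
  expect_equal(cs$sensitivity, 2 / 3)
  expect_equal(cs$specificity, 2 / 3)
  expect_equal(cs$fnr, 1 / 3)
  expect_equal(cs$fpr, 1 / 3)
  one_class <- confusion_stats(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(one_class$specificity))
  expect_error(confusion_stats(TRUE, c(TRUE, FALSE)), "length")
})

test_that("AUC agrees with an independent ROC implementation when available", {
  set.seed(76)
  ts <- stats::rnorm(300, 0.7); ns <- stats::rnorm(400)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 300), rep(0, 400)), predictor = c(ts, ns),
    quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(ts, ns), ref, tolerance = 1e-9)
})
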