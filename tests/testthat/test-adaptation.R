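test_that("component responsibilities agree with the posterior oracle", {
  set.seed(51)
  g <- random_gmm(4L, 5L)
  X <- sample_gmm(g, 200L)
  cl <- crydx:::gmm_component_logliks(X, g)
  post <- exp(cl - crydx:::logsumexp_rows(cl))    # standard posteriors
  for (k in 1:4) {
    r <- component_responsibilities(X, g, k)
    # c_k * w_t equals the posterior Pr(k | x_t)
    expect_equal(g$weights[k] * r$w, post[, k], tolerance = 1e-10)
    expect_equal(r$n_k, sum(post[, k]), tolerance = 1e-10)
    expect_equal(sum(r$gamma), 1, tolerance = 1e-12)
    expect_true(r$valid)
  }
  expect_error(component_responsibilities(X, g, 9L), "out of range")
})

test_that("K = 1 BML recovers the sample moments of the adaptation data", {
  set.seed(52)
  g1 <- gmm_params(1, matrix(c(0, 0), 1L), matrix(c(1, 1), 1L))
  X <- matrix(stats::rnorm(4000, mean = 2, sd = 1.5), 2000L, 2L)
  m <- adapt_bml(g1, X, adaptation_config(2L, n_sweeps = 1L,
                                          per_component_iters = 1L))
  # with a single component every gamma_t = 1/T: exact sample moments
  expect_equal(drop(m$means), colMeans(X), tolerance = 1e-10)
  expect_equal(drop(m$variances),
               apply(X, 2L, function(c) mean((c - mean(c))^2)),
               tolerance = 1e-10)
  expect_equal(m$weights, 1)
})

test_that("method 4 adapts means only; methods keep the simplex and floor", {
  set.seed(53)
  ubm <- random_gmm(5L, 6L)
  X <- sample_gmm(ubm, 3000L) + 0.6
  for (method in 1:4) {
    m <- adapt_gmm(ubm, X, method)
    expect_equal(sum(m$weights), 1, tolerance = 1e-9)
    expect_true(all(m$weights >= 0))
    expect_true(all(m$variances > 0))
  }
  m4 <- adapt_gmm(ubm, X, 4L)
  expect_identical(m4$weights, ubm$weights)
  expect_identical(m4$variances, ubm$variances)
  expect_false(isTRUE(all.equal(m4$means, ubm$means)))
  m1 <- adapt_gmm(ubm, X, 1L)
  expect_identical(m1$weights, ubm$weights)
  expect_identical(m1$variances, ubm$variances)
})

test_that("MAP adaptation matches the textbook relevance-factor formula", {
  set.seed(54)
  ubm <- random_gmm(3L, 4L)
  X <- sample_gmm(ubm, 400L) + 0.3
  r <- 16
  m <- adapt_map(ubm, X, r = r)
  cl <- crydx:::gmm_component_logliks(X, ubm)
  post <- exp(cl - crydx:::logsumexp_rows(cl))
  for (k in 1:3) {
    n_k <- sum(post[, k])
    E_k <- colSums(post[, k] * X) / n_k
    a <- n_k / (n_k + r)
    expect_equal(m$means[k, ], a * E_k + (1 - a) * ubm$means[k, ],
                 tolerance = 1e-10)
  }
  # when n_i = r the adapted mean is the exact midpoint
  g1 <- gmm_params(1, matrix(0, 1L, 1L), matrix(1, 1L, 1L))
  X16 <- matrix(rep(2, 16), 16L, 1L)       # posterior count is exactly 16
  mid <- adapt_map(g1, X16, r = 16)
  expect_equal(drop(mid$means), 1, tolerance = 1e-12)
  expect_error(adapt_map(ubm, X, r = 0), "positive")
})

test_that("coupled adaptation interpolates between UBM and BML limits", {
  set.seed(55)
  ubm <- random_gmm(3L, 4L)
  X <- sample_gmm(ubm, 2000L) + 0.5
  bml <- adapt_bml(ubm, X, adaptation_config(2L))
  # tiny relevance factor: alpha -> 1, coupled -> BML moments
  near_bml <- adapt_coupled(ubm, X, adaptation_config(3L, relevance_factor = 1e-6))
  expect_equal(near_bml$means, bml$means, tolerance = 1e-4)
  # huge relevance factor: alpha -> 0, coupled -> UBM
  near_ubm <- adapt_coupled(ubm, X, adaptation_config(3L, relevance_factor = 1e9))
  expect_equal(near_ubm$means, ubm$means, tolerance = 1e-4)
  expect_equal(near_ubm$variances, ubm$variances, tolerance = 1e-3)
  # weights are never touched by method 3
  mid <- adapt_gmm(ubm, X, 3L)
  expect_identical(mid$weights, ubm$weights)
})

test_that("fast sweeping BML equals sequential per-component updates", {
  set.seed(56)
  ubm <- random_gmm(6L, 5L)
  X <- sample_gmm(ubm, 600L) + 0.4
  cfg <- adaptation_config(2L)
  fast <- adapt_bml(ubm, X, cfg)
  slow <- ubm
  vf <- crydx:::floor_for(ubm, X)
  for (s in seq_len(cfg$n_sweeps)) {
    nk <- vapply(1:6, function(k)
      component_responsibilities(X, slow, k)$n_k, numeric(1))
    for (k in order(nk, decreasing = TRUE)) {
      if (nk[k] < cfg$min_count) next
      slow <- bml_update_component(slow, X, k, iters = cfg$per_component_iters,
                                   update_variance = TRUE,
                                   update_weights = TRUE,
                                   renormalize_weights = TRUE, var_floor = vf)
    }
  }
  expect_equal(fast$weights, slow$weights, tolerance = 1e-10)
  expect_equal(fast$means, slow$means, tolerance = 1e-10)
  expect_equal(fast$variances, slow$variances, tolerance = 1e-10)
})

test_that("adaptation leaves a self-consistent model near the UBM", {
  # adapting on data drawn from the UBM itself must not move the model far
  set.seed(57)
  ubm <- random_gmm(4L, 6L)
  X <- sample_gmm(ubm, 20000L)
  for (method in c(1L, 3L)) {
    m <- adapt_gmm(ubm, X, method)
    expect_lt(max(abs(m$means - ubm$means) / sqrt(ubm$variances)), 0.2)
  }
})

test_that("adaptation recovers a known mean shift", {
  set.seed(58)
  ubm <- random_gmm(3L, 5L)
  delta <- 1.0
  shifted <- ubm
  shifted$means <- shifted$means + delta * sqrt(ubm$variances)
  X <- sample_gmm(shifted, 20000L)
  for (method in 1:4) {
    m <- adapt_gmm(ubm, X, method)
    moved <- (m$means - ubm$means) / sqrt(ubm$variances)
    # every component moves a substantial fraction of the true shift,
    # in the right direction
    expect_gt(min(rowMeans(moved)), 0.5 * delta)
  }
})

test_that("adaptation input validation", {
  ubm <- random_gmm(2L, 3L, seed = 59L)
  expect_error(adapt_gmm(ubm, matrix(0, 0L, 3L), 2L), "empty")
  expect_error(adaptation_config(5L), "method")
  expect_error(adapt_bml(ubm, matrix(0, 5L, 3L), adaptation_config(1L)),
               "methods 2 and 4")
})
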