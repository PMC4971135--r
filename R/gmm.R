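# Diagonal-covariance Gaussian mixture models: density, EM training, pooling.

#' Construct a diagonal-covariance GMM
#'
#' Mixture weights must be a simplex (nonnegative, summing to 1) and all
#' diagonal variances strictly positive; these constraints are validated on
#' construction and maintained by every operation in the package.
#'
#' @param weights length-K weight vector.
#' @param means K x D matrix of component means.
#' @param variances K x D matrix of diagonal covariance entries.
#' @param tag optional label (e.g. which UBM or class the model represents).
#' @param var_floor optional length-D variance floor carried with the model
#'   and honored by adaptation.
#' @return an object of class `gmm`.
#' @export
gmm_params <- function(weights, means, variances, tag = NULL, var_floor = NULL) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  K <- length(weights)
  if (nrow(means) != K || nrow(variances) != K || ncol(means) != ncol(variances))
    stop("inconsistent GMM dimensions")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be nonnegative and sum to 1")
  if (any(variances <= 0)) stop("variances must be strictly positive")
  structure(list(weights = pmax(weights, 0), means = means,
                 variances = variances, tag = tag, var_floor = var_floor),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm: K=%d, D=%d%s>\n", length(x$weights), ncol(x$means),
              if (is.null(x$tag)) "" else paste0(", tag=", x$tag)))
  invisible(x)
}

n_components <- function(gmm) length(gmm$weights)

as_feature_matrix <- function(X) {
  if (inherits(X, "feature_sequence")) X$X
  else if (is.matrix(X)) X
  else matrix(X, nrow = 1L)
}

# T x K matrix of log(c_k) + log N(x_t | mu_k, Sigma_k), diagonal covariance.
# Written as two matrix products so scoring long sequences stays fast.
gmm_component_logliks <- function(X, gmm) {
  X <- as_feature_matrix(X)
  D <- ncol(gmm$means)
  if (ncol(X) != D) stop("feature dimension does not match the model")
  iv <- 1 / gmm$variances                        # K x D
  quad <- (X^2) %*% t(iv) - 2 * (X %*% t(gmm$means * iv))
  const <- log(gmm$weights) -
    0.5 * (D * log(2 * pi) + rowSums(log(gmm$variances)) +
             rowSums(gmm$means^2 * iv))
  sweep(-0.5 * quad, 2L, const, `+`)
}

# single-component column of the matrix above
gmm_component_loglik_col <- function(X, weight, mu, v) {
  D <- length(mu)
  q <- drop((X^2) %*% (1 / v)) - 2 * drop(X %*% (mu / v)) + sum(mu^2 / v)
  log(weight) - 0.5 * (D * log(2 * pi) + sum(log(v)) + q)
}

logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  bad <- !is.finite(mx)
  res <- mx + log(rowSums(exp(m - mx)))
  res[bad] <- -Inf
  res
}

#' Log density of a GMM
#'
#' `log F(x | lambda)` computed in the log domain via log-sum-exp over the
#' weighted diagonal Gaussian components.
#'
#' @param x a D-vector, a T x D matrix, or a [feature_sequence()].
#' @param gmm a [gmm_params()] model.
#' @return scalar for a single vector, otherwise a length-T vector.
#' @export
gmm_logpdf <- function(x, gmm) {
  vec_in <- !is.matrix(x) && !inherits(x, "feature_sequence")
  ll <- logsumexp_rows(gmm_component_logliks(x, gmm))
  if (vec_in) ll[1L] else ll
}

#' Duration-normalized average log-likelihood
#'
#' `(1/T) * sum_t log F(x_t | lambda)`; the 1/T factor removes the effect of
#' sequence duration so scores of short and long cry units are comparable.
#'
#' @param X a T x D matrix or [feature_sequence()] with `T >= 1`.
#' @param gmm a [gmm_params()] model.
#' @return scalar average log-likelihood (nats per frame).
#' @export
avg_loglik <- function(X, gmm) {
  X <- as_feature_matrix(X)
  if (nrow(X) == 0L) stop("empty sequence")
  mean(gmm_logpdf(X, gmm))
}

# k-means++ seeding: spread initial centers proportionally to squared distance.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], `-`)^2)
  for (k in seq_len(K - 1L) + 1L) {
    p <- d2 / sum(d2)
    centers[k, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ], `-`)^2))
  }
  centers
}

#' Train a diagonal-covariance GMM with EM
#'
#' Initialization is k-means++ followed by a short Lloyd refinement; the EM
#' loop then alternates soft assignments and moment updates, flooring each
#' variance at `var_floor_factor` times the global per-dimension variance.
#' The per-iteration average log-likelihood is non-decreasing; training stops
#' at `max_iters` or when its relative change falls below `tol`. A component
#' that loses all soft mass is re-seeded at the lowest-likelihood frame.
#'
#' @param X T x D matrix (or [feature_sequence()]) of training frames.
#' @param K number of mixture components.
#' @param max_iters maximum EM iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param var_floor_factor variance floor as a fraction of the global
#'   per-dimension variance (default 1e-3).
#' @param seed RNG seed for reproducible initialization.
#' @param tag optional label stored on the model.
#' @return a [gmm_params()] model; attribute `loglik_trace` holds the
#'   per-iteration average log-likelihoods.
#' @export
train_gmm_em <- function(X, K, max_iters = 100L, tol = 1e-6,
                         var_floor_factor = 1e-3, seed = NULL, tag = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (K > n) stop("K exceeds the number of training frames")
  if (n < 10L * K)
    warning("fewer than 10 frames per component; estimates may be unstable")
  if (!is.null(seed)) set.seed(seed)

  gvar <- apply(X, 2L, stats::var)
  gvar[gvar <= 0] <- 1
  floor_v <- pmax(var_floor_factor * gvar, .Machine$double.eps)

  if (K == 1L) {
    mu <- matrix(colMeans(X), 1L, D)
    v <- matrix(pmax(apply(X, 2L, function(c) mean((c - mean(c))^2)), floor_v), 1L, D)
    fit <- gmm_params(1, mu, v, tag = tag, var_floor = floor_v)
    attr(fit, "loglik_trace") <- avg_loglik(X, fit)
    return(fit)
  }

  centers <- kmeanspp_centers(X, K)
  km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 20L,
                                       algorithm = "Lloyd"))
  means <- km$centers
  weights <- pmax(tabulate(km$cluster, K), 1) / max(sum(pmax(tabulate(km$cluster, K), 1)), 1)
  weights <- weights / sum(weights)
  variances <- matrix(rep(gvar, each = K), K, D)
  for (k in seq_len(K)) {
    idx <- which(km$cluster == k)
    if (length(idx) > 1L)
      variances[k, ] <- pmax(apply(X[idx, , drop = FALSE], 2L,
                                   function(c) mean((c - mean(c))^2)), floor_v)
  }

  model <- gmm_params(weights, means, variances, tag = tag, var_floor = floor_v)
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iters)) {
    cl <- gmm_component_logliks(X, model)
    tot <- logsumexp_rows(cl)
    trace <- c(trace, mean(tot))
    resp <- exp(cl - tot)                     # T x K posteriors
    nk <- colSums(resp)
    empty <- which(nk < .Machine$double.eps)
    if (length(empty) > 0L) {
      warning("re-seeding ", length(empty), " empty component(s)")
      worst <- order(tot)[seq_along(empty)]
      for (j in seq_along(empty)) {
        model$means[empty[j], ] <- X[worst[j], ]
        model$variances[empty[j], ] <- gvar
        model$weights[empty[j]] <- 1 / n
      }
      model$weights <- model$weights / sum(model$weights)
      next
    }
    w <- nk / n
    mu <- sweep(crossprod(resp, X), 1L, nk, `/`)
    ex2 <- sweep(crossprod(resp, X^2), 1L, nk, `/`)
    v <- pmax(ex2 - mu^2, rep(floor_v, each = K))
    model <- gmm_params(w / sum(w), mu, v, tag = tag, var_floor = floor_v)
    if (is.finite(prev) && abs(trace[iter] - prev) <= tol * abs(prev)) break
    prev <- trace[iter]
  }
  attr(model, "loglik_trace") <- trace
  model
}

#' Pool training frames with balanced class contributions
#'
#' Builds the stacked frame matrix used to train a universal background
#' model. In `pathology_independent` mode every pathology subclass
#' contributes the same number of frames. In `health_independent` mode the
#' pooled sick total is first matched to the healthy total (each sick
#' subclass contributing equally), then the healthy class is subsampled to
#' the same total, so the two sides of the detector are balanced. Frames are
#' subsampled without replacement (seeded); a subclass smaller than its
#' equal share is topped up by resampling with replacement, with a warning.
#'
#' @param corpora named list of per-class frame matrices; in
#'   `health_independent` mode the healthy class is named `"Healthy"`.
#' @param mode `"health_independent"` or `"pathology_independent"`.
#' @param seed RNG seed.
#' @return stacked frame matrix with attribute `class_counts`.
#' @export
pool_balanced <- function(corpora, mode = c("health_independent",
                                            "pathology_independent"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(corpora, nrow, integer(1L))
  zero <- names(counts)[counts == 0L]
  if (length(zero) > 0L)
    stop("class with zero frames: ", paste(zero, collapse = ", "))

  take <- function(X, m) {
    n <- nrow(X)
    if (m <= n) X[sample.int(n, m), , drop = FALSE]
    else {
      warning("class smaller than its balanced share; resampling with replacement")
      X[sample.int(n, m, replace = TRUE), , drop = FALSE]
    }
  }

  if (mode == "pathology_independent") {
    if (length(corpora) < 2L) stop("need at least two pathology classes")
    m <- min(counts)
    picked <- lapply(corpora, take, m = m)
  } else {
    if (!"Healthy" %in% names(corpora)) stop("missing class: Healthy")
    sick <- corpora[setdiff(names(corpora), "Healthy")]
    if (length(sick) == 0L) stop("missing class: at least one sick class")
    total <- min(counts[["Healthy"]], sum(vapply(sick, nrow, integer(1L))))
    per_sick <- total %/% length(sick)
    picked <- c(list(Healthy = take(corpora$Healthy, per_sick * length(sick))),
                lapply(sick, take, m = per_sick))
  }
  out <- do.call(rbind, picked)
  attr(out, "class_counts") <- vapply(picked, nrow, integer(1L))
  out
}

#' Write/read a GMM as JSON
#'
#' @param gmm a [gmm_params()] model.
#' @param path JSON path.
#' @export
write_gmm <- function(gmm, path) {
  jsonlite::write_json(list(K = n_components(gmm), weights = gmm$weights,
                            means = gmm$means, variances = gmm$variances,
                            tag = gmm$tag, var_floor = gmm$var_floor),
                       path, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gmm_params(obj$weights, obj$means, obj$variances, tag = obj$tag,
             var_floor = obj$var_floor)
}
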