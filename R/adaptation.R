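# Deriving class models from a UBM: mean-only MAP and three boosted-mixture-
# learning (BML) variants that refine one component at a time while the rest
# of the mixture is held fixed.

#' Adaptation configuration
#'
#' Four methods are supported:
#' \enumerate{
#'   \item mean-only MAP (Bayesian) adaptation with relevance factor `r`;
#'   \item BML adaptation of means and variances;
#'   \item BML estimates coupled with the UBM estimates through a single
#'     coefficient `alpha_i = n_i / (n_i + r)` per component;
#'   \item BML adaptation of means only.
#' }
#'
#' @param method integer 1--4.
#' @param relevance_factor relevance factor `r` (default 16) controlling the
#'   balance between old and new estimates in methods 1 and 3.
#' @param n_sweeps number of passes over all components in BML (default 2).
#' @param per_component_iters fixed-point iterations per component per sweep
#'   (default 3).
#' @param renormalize_weights rescale the untouched weights after each
#'   per-component weight update so the simplex constraint holds (default
#'   `TRUE`).
#' @param update_weights update mixture weights in BML? Defaults to `TRUE`
#'   for method 2/3 and `FALSE` for method 4.
#' @param min_count skip components whose effective frame count falls below
#'   this threshold (default 1 frame).
#' @param literal_weight_update use the literal self-multiplying weight
#'   update `c <- mean(c * w)` instead of the posterior-mean reading
#'   (default `FALSE`; for comparison only).
#' @return an `adaptation_config` list.
#' @export
adaptation_config <- function(method, relevance_factor = 16, n_sweeps = 2L,
                              per_component_iters = 3L,
                              renormalize_weights = TRUE,
                              update_weights = NULL, min_count = 1.0,
                              literal_weight_update = FALSE) {
  stopifnot(method %in% 1:4, relevance_factor > 0, n_sweeps >= 1,
            per_component_iters >= 1)
  if (is.null(update_weights)) update_weights <- method %in% c(2L, 3L)
  structure(list(method = as.integer(method),
                 relevance_factor = relevance_factor,
                 n_sweeps = as.integer(n_sweeps),
                 per_component_iters = as.integer(per_component_iters),
                 renormalize_weights = isTRUE(renormalize_weights),
                 update_weights = isTRUE(update_weights),
                 min_count = min_count,
                 literal_weight_update = isTRUE(literal_weight_update)),
            class = "adaptation_config")
}

#' Per-component sample weights and normalized responsibilities
#'
#' For component k, the sample weight of frame t is
#' `w_t = f_k(x_t) / F(x_t)`: the ratio of the component density to the full
#' mixture density, computed in the log domain. `gamma_t = w_t / sum(w)` are
#' the normalized responsibilities used for moment updates, and
#' `n_k = sum(c_k * w_t)` is the effective frame count. Note that `c_k * w_t`
#' is the standard posterior probability of component k given the frame.
#'
#' @param X frames (matrix or [feature_sequence()]).
#' @param gmm a [gmm_params()] model.
#' @param k component index.
#' @return list with `w`, `gamma`, `n_k` and `valid` (FALSE when the
#'   component receives no mass at all).
#' @export
component_responsibilities <- function(X, gmm, k) {
  X <- as_feature_matrix(X)
  if (nrow(X) == 0L) stop("empty sequence")
  K <- n_components(gmm)
  if (k < 1L || k > K) stop("component index out of range")
  cl <- gmm_component_logliks(X, gmm)           # includes log weights
  logF <- logsumexp_rows(cl)
  log_fk <- cl[, k] - log(gmm$weights[k])       # component density alone
  w <- exp(log_fk - logF)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0)
    return(list(w = w, gamma = rep(NA_real_, length(w)), n_k = 0, valid = FALSE))
  list(w = w, gamma = w / sw, n_k = sum(gmm$weights[k] * w), valid = TRUE)
}

floor_for <- function(gmm, X) {
  if (!is.null(gmm$var_floor)) return(gmm$var_floor)
  gv <- apply(as_feature_matrix(X), 2L, stats::var)
  pmax(1e-3 * ifelse(gv > 0, gv, 1), .Machine$double.eps)
}

#' Refine one mixture component by the BML fixed-point update
#'
#' Iterates, `iters` times, the update that re-estimates component k from its
#' sample weights while all other components stay fixed: the new weight is
#' the mean posterior responsibility `mean(c_k * w_t)`, the new mean is
#' `sum(gamma_t * x_t)`, and (optionally) the new diagonal variance is
#' `sum(gamma_t * (x_t - mu)^2)`, floored. When the weight is updated the
#' remaining weights are rescaled by `(1 - c_new) / (1 - c_old)` so the
#' mixture stays on the simplex.
#'
#' @param gmm the current model.
#' @param X adaptation frames.
#' @param k component index.
#' @param iters fixed-point iterations (default 3).
#' @param update_variance update the diagonal variance? Default `TRUE`.
#' @param update_weights update the component weight? Default `TRUE`.
#' @param renormalize_weights rescale the other weights (default `TRUE`).
#' @param literal_weight_update see [adaptation_config()].
#' @param var_floor length-D variance floor (defaults to the model's).
#' @return the model with component k updated; unchanged (with a warning) if
#'   the component receives no responsibility mass.
#' @export
bml_update_component <- function(gmm, X, k, iters = 3L, update_variance = TRUE,
                                 update_weights = TRUE,
                                 renormalize_weights = TRUE,
                                 literal_weight_update = FALSE,
                                 var_floor = NULL) {
  X <- as_feature_matrix(X)
  if (is.null(var_floor)) var_floor <- floor_for(gmm, X)
  T_ <- nrow(X)
  for (it in seq_len(iters)) {
    r <- component_responsibilities(X, gmm, k)
    if (!r$valid) {
      warning("component ", k, " has zero responsibility mass; skipped")
      return(gmm)
    }
    c_old <- gmm$weights[k]
    c_new <- if (literal_weight_update) mean(c_old * r$w)
             else sum(c_old * r$w) / T_
    mu_new <- colSums(r$gamma * X)
    gmm$means[k, ] <- mu_new
    if (update_variance) {
      z <- sweep(X, 2L, mu_new, `-`)
      gmm$variances[k, ] <- pmax(colSums(r$gamma * z^2), var_floor)
    }
    if (update_weights) {
      c_new <- min(max(c_new, 0), 1)
      gmm$weights[k] <- c_new
      if (renormalize_weights && c_old < 1) {
        others <- setdiff(seq_along(gmm$weights), k)
        gmm$weights[others] <- gmm$weights[others] * (1 - c_new) / (1 - c_old)
      }
      gmm$weights <- gmm$weights / sum(gmm$weights)
    }
  }
  gmm
}

#' BML adaptation of a UBM (methods 2 and 4)
#'
#' Sweeps over the components in order of decreasing effective frame count
#' (recomputed at the start of every sweep), applying
#' [bml_update_component()] to each. Method 2 refines means and variances;
#' method 4 refines means only, leaving weights and variances identical to
#' the UBM's. Components with effective count below `config$min_count` are
#' skipped.
#'
#' @param ubm the universal background model ([gmm_params()]).
#' @param X adaptation frames for one subclass.
#' @param config an [adaptation_config()] with method 2 or 4.
#' @return the adapted [gmm_params()] model.
#' @export
adapt_bml <- function(ubm, X, config = adaptation_config(2L)) {
  if (!config$method %in% c(2L, 4L))
    stop("adapt_bml handles methods 2 and 4 only")
  X <- as_feature_matrix(X)
  if (nrow(X) == 0L) stop("empty adaptation data")
  update_variance <- config$method == 2L
  var_floor <- floor_for(ubm, X)
  model <- ubm
  K <- n_components(model)
  if (config$renormalize_weights || !config$update_weights) {
    # fast path: cache the T x K component log-likelihood matrix and refresh
    # only the column of the component being refined (plus a constant shift
    # of the others when weights are renormalized)
    CL <- gmm_component_logliks(X, model)
    T_ <- nrow(X)
    for (sweep_i in seq_len(config$n_sweeps)) {
      post_nk <- colSums(exp(CL - logsumexp_rows(CL)))
      for (k in order(post_nk, decreasing = TRUE)) {
        if (post_nk[k] < config$min_count) next
        for (it in seq_len(config$per_component_iters)) {
          logF <- logsumexp_rows(CL)
          w <- exp(CL[, k] - log(model$weights[k]) - logF)
          sw <- sum(w)
          if (!is.finite(sw) || sw <= 0) {
            warning("component ", k, " has zero responsibility mass; skipped")
            break
          }
          gamma <- w / sw
          c_old <- model$weights[k]
          model$means[k, ] <- colSums(gamma * X)
          if (update_variance) {
            z <- sweep(X, 2L, model$means[k, ], `-`)
            model$variances[k, ] <- pmax(colSums(gamma * z^2), var_floor)
          }
          if (config$update_weights) {
            c_new <- if (config$literal_weight_update) mean(c_old * w)
                     else sum(c_old * w) / T_
            c_new <- min(max(c_new, 0), 1)
            model$weights[k] <- c_new
            if (c_old < 1 && c_new < 1) {
              rho <- (1 - c_new) / (1 - c_old)
              model$weights[-k] <- model$weights[-k] * rho
              CL[, -k] <- CL[, -k] + log(rho)
            }
            model$weights <- model$weights / sum(model$weights)
          }
          CL[, k] <- gmm_component_loglik_col(X, model$weights[k],
                                              model$means[k, ],
                                              model$variances[k, ])
        }
      }
    }
  } else {
    for (sweep_i in seq_len(config$n_sweeps)) {
      nk <- vapply(seq_len(K), function(k)
        component_responsibilities(X, model, k)$n_k, numeric(1L))
      for (k in order(nk, decreasing = TRUE)) {
        if (nk[k] < config$min_count) next
        model <- bml_update_component(model, X, k,
                                      iters = config$per_component_iters,
                                      update_variance = update_variance,
                                      update_weights = config$update_weights,
                                      renormalize_weights = config$renormalize_weights,
                                      literal_weight_update = config$literal_weight_update,
                                      var_floor = var_floor)
      }
    }
  }
  model$tag <- paste0(ubm$tag %||% "ubm", ":bml", config$method)
  model
}

#' Mean-only MAP (Bayesian) adaptation of a UBM (method 1)
#'
#' Classic relevance-factor MAP restricted to the means: with posterior
#' counts `n_i = sum_t Pr(i | x_t)` and posterior means
#' `E_i = sum_t Pr(i | x_t) x_t / n_i`, each mean moves to
#' `alpha_i * E_i + (1 - alpha_i) * mu_i` where
#' `alpha_i = n_i / (n_i + r)`. Weights and variances are left untouched.
#'
#' @param ubm the universal background model.
#' @param X adaptation frames.
#' @param r relevance factor (default 16).
#' @return the adapted [gmm_params()] model.
#' @export
adapt_map <- function(ubm, X, r = 16) {
  X <- as_feature_matrix(X)
  if (nrow(X) == 0L) stop("empty adaptation data")
  if (r <= 0) stop("relevance factor must be positive")
  cl <- gmm_component_logliks(X, ubm)
  post <- exp(cl - logsumexp_rows(cl))          # T x K posteriors
  n_i <- colSums(post)
  alpha <- n_i / (n_i + r)
  model <- ubm
  for (k in which(n_i > 0)) {
    E_k <- colSums(post[, k] * X) / n_i[k]
    model$means[k, ] <- alpha[k] * E_k + (1 - alpha[k]) * ubm$means[k, ]
  }
  model$tag <- paste0(ubm$tag %||% "ubm", ":map")
  model
}

#' Coupled BML/UBM adaptation (method 3)
#'
#' First computes BML estimates of the means and variances as in
#' [adapt_bml()] (method 2), then couples them with the UBM estimates using a
#' single coefficient per component, `alpha_i = n_i / (n_i + r)` with the
#' occupation counts taken under the UBM:
#' `mu' = alpha * mu_BML + (1 - alpha) * mu_UBM`, and the variances are
#' combined by second-moment matching,
#' `Sigma' = alpha * (Sigma_BML + mu_BML^2) + (1 - alpha) * (Sigma_UBM +
#' mu_UBM^2) - mu'^2`, floored. Weights are left at the UBM's values.
#'
#' @param ubm the universal background model.
#' @param X adaptation frames.
#' @param config an [adaptation_config()] (method 3); its
#'   `relevance_factor` supplies `r`.
#' @return the adapted [gmm_params()] model.
#' @export
adapt_coupled <- function(ubm, X, config = adaptation_config(3L)) {
  X <- as_feature_matrix(X)
  if (nrow(X) == 0L) stop("empty adaptation data")
  bml_cfg <- config
  bml_cfg$method <- 2L
  bml <- adapt_bml(ubm, X, bml_cfg)
  cl <- gmm_component_logliks(X, ubm)
  post <- exp(cl - logsumexp_rows(cl))
  n_i <- colSums(post)
  alpha <- n_i / (n_i + config$relevance_factor)
  var_floor <- floor_for(ubm, X)
  model <- ubm
  for (k in seq_len(n_components(ubm))) {
    mu_new <- alpha[k] * bml$means[k, ] + (1 - alpha[k]) * ubm$means[k, ]
    m2_new <- alpha[k] * (bml$variances[k, ] + bml$means[k, ]^2) +
      (1 - alpha[k]) * (ubm$variances[k, ] + ubm$means[k, ]^2)
    model$means[k, ] <- mu_new
    model$variances[k, ] <- pmax(m2_new - mu_new^2, var_floor)
  }
  model$tag <- paste0(ubm$tag %||% "ubm", ":coupled")
  model
}

#' Adapt a UBM to a subclass by any of the four methods
#'
#' Dispatcher over [adapt_map()] (method 1), [adapt_bml()] (methods 2 and 4)
#' and [adapt_coupled()] (method 3).
#'
#' @param ubm the universal background model.
#' @param X adaptation frames.
#' @param method integer 1--4, or an [adaptation_config()].
#' @param ... further arguments passed to [adaptation_config()] when
#'   `method` is an integer.
#' @return the adapted [gmm_params()] model.
#' @export
adapt_gmm <- function(ubm, X, method = 2L, ...) {
  config <- if (inherits(method, "adaptation_config")) method
            else adaptation_config(method, ...)
  switch(config$method,
         adapt_map(ubm, X, r = config$relevance_factor),
         adapt_bml(ubm, X, config),
         adapt_coupled(ubm, X, config),
         adapt_bml(ubm, X, config))
}
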